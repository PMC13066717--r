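# Treatment-period presets for the five multi-site AUD pharmacotherapy
# trials emulated by the synthetic generator. Titration/taper weeks are
# contained within treatment_weeks and kept as metadata only: endpoint
# windows anchor strictly at the last treatment day.
studies:
  - study_name: combine
    treatment_weeks: 16
    titration_weeks: 0
    taper_weeks: 0
    grams_per_drink: 14.0
  - study_name: horizant
    treatment_weeks: 26
    titration_weeks: 1
    taper_weeks: 1
    grams_per_drink: 14.0
  - study_name: levetiracetam
    treatment_weeks: 16
    titration_weeks: 4
    taper_weeks: 2
    grams_per_drink: 14.0
  - study_name: varenicline
    treatment_weeks: 13
    titration_weeks: 1
    taper_weeks: 0
    grams_per_drink: 14.0
  - study_name: quetiapine
    treatment_weeks: 12
    titration_weeks: 2
    taper_weeks: 1
    grams_per_drink: 14.0
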