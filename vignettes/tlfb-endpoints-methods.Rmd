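---
title: "Deriving and analyzing TLFB drinking endpoints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and analyzing TLFB drinking endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlfbtrials)
```

This vignette is the package's account of its methods: the endpoint
definitions and their numerical conventions, the statistical stage, the
synthetic trial generator and what it does and does not emulate, and the
design choices that were genuinely open.

## The calendar model

A participant's drinking history is a timeline follow-back (TLFB) calendar:
one record per study day with the reported number of standard drinks, or a
missing flag when nothing was reported. Days are indexed on a 0-based axis
with randomization/first dosing at day 0, so screening and pre-screening
days are negative. This makes "prior to randomization" a scan over negative
days and keeps window arithmetic sign-transparent. The calendar declares two
anchors: the screening day (negative) and the last treatment day
(`treatment_weeks * 7`).

Two assessment windows drive everything: the 28 days ending the day before
an anchor (`direction = "before"`, used for the baseline month before
screening) and the 28 days ending *at* an anchor (`direction = "ending_at"`,
used for the endpoint window at the end of treatment). `extract_window()`
always returns exactly the requested number of records; days the calendar
does not contain come back flagged missing, so downstream code never has to
distinguish "absent" from "unreported". Endpoint windows anchor strictly at
the last treatment day even when a study ends with a taper week; taper and
titration weeks are retained as metadata only.

## WHO risk drinking levels

Mean grams/day over a 28-day window (standard drink = 14 g, the US
convention; configurable, since the trials the package emulates are all
US-based and report drinks, not grams) maps to the ordinal WHO risk
drinking level. The bands are half-open on the left and closed on the
right — male low = (0, 40], medium = (40, 60], high = (60, 100], very high
= (100, Inf); female bands are (0, 20], (20, 40], (40, 60], (60, Inf). The
"40–60 g" phrasing conventional in this literature is ambiguous at the
boundary; ties go to the *lower* band because "up to 40 g" reads as
inclusive. A window classifies as abstinent only when it contains no
drinking day at all, not merely when the mean is zero; this makes the
five levels a strict ordinal scale on which "two levels below medium" is
well-defined (it forces complete abstinence), so the WHO 2+ reduction rule
is plain integer subtraction of level codes with no special cases.

A window containing any missing day has an undefined mean. The
classification layer only flags this; the *policy* belongs to the endpoints
layer, which by default voids the window (the strictest reading of recoding
dropouts and missing data to "no change"). An alternative policy that
classifies on the observed days only is available as `observed_only =
TRUE`, default off, because mid-window gaps in real TLFB data are common
enough that the choice deserves to be explicit.

## Endpoints and imputation

Total abstinence and no-heavy-drinking are computed over the entire
treatment period `[0, treatment_end_day]` under worst-case imputation: an
unreported day is treated as a drinking day (and a heavy drinking day), so
any gap or dropout fails both endpoints. This is deliberately monotone —
deleting an observed day can never flip either endpoint from false to true,
and the test suite asserts exactly that property. The heavy-day threshold
is >= 5 standard drinks for men and >= 4 for women (the NIAAA convention;
the threshold is a parameter because trial protocols occasionally differ).

DSLD counts consecutive observed zero-drink days backwards from day −1 and
stops at the first drinking, missing, or absent day. When the entire
observed history is abstinent the count is capped at the observed history
length — no extrapolation beyond the calendar. Days between screening and
randomization participate automatically because they are calendar days like
any others.

Research completion is presence of a TLFB record on the final treatment
day, independent of what was drunk. These definitions interlock:
abstinence implies no heavy days implies a fully observed endpoint window,
and a non-completer can meet none of the three drinking endpoints.

## Harmonization

Per-study baseline tables are collapsed to a shared binary covariate
scheme: married/cohabitating vs other marital states; employed full/part
time vs other statuses; income dichotomized at $60,000/year (chosen in the
source literature as the split closest to even); 12+ years of education;
10+ cigarettes/day; THC urine-screen positivity; and non-exclusive White,
Black, Hispanic indicators entered simultaneously in models, with
participants in none of the three as the implicit reference. The sparse
remaining race categories are retained in the data but get no indicator;
their counts are written to the exclusion log. Category dictionaries live
in configuration, not code, because the five emulated trials used different
instruments; the packaged defaults match the synthetic generator's
vocabulary. Participants whose baseline level is abstinent or low risk are
excluded — a two-level reduction is arithmetically impossible for them —
with conservation-checked logging. (A note for readers of the source
literature: the published placebo-subset sample size differs between the
text, n = 610, and the baseline table, n = 607; the discrepancy is in the
source and is preserved as a note rather than resolved.)

## The statistical stage

Each binary outcome is modeled by maximum-likelihood logistic regression
(IRLS via `glm`) on study, arm (omitted in the placebo-only subset),
baseline risk level with medium as reference, DSLD, age, and the
demographic covariates. Per-coefficient inference is by Wald tests, to
mirror the per-coefficient p columns conventional in this literature;
multi-level categorical predictors (study, baseline level) additionally get
a single likelihood-ratio test of the dummy block, since a block-level p is
the quantity usually reported and no test is named for it in the source
literature. Significance is flagged at the Bonferroni threshold alpha/m
with m = 4 modeled outcomes, 0.05/4 = 0.0125. Fits are complete-case
within each model with a logged dropped-row count; separation or
non-convergence flags the fit rather than silently reporting it.

ROC analysis evaluates every achievable threshold — midpoints between
consecutive distinct predictor values plus the two infinite ends — under
the rule "predict success when the predictor exceeds the threshold".
Integer predictors such as DSLD therefore yield half-integer candidate
cutoffs, which is why published optima land on values like 3.5 or 5.5
days. Youden's J picks the optimum; ties break toward the smallest
threshold so reported cutoffs are conservative. AUC is the trapezoidal
area under the coordinate table, which a test verifies against an
independent ROC implementation.

Contingency tables at a cutoff use Pearson chi-squared without continuity
correction; two-group continuous comparisons default to the pooled-variance
t-test with Welch available by flag (published t statistics at these sample
sizes are consistent with the pooled form), and three or more groups use
one-way ANOVA.

## The synthetic generator

The generator exists because the source clinical datasets are
controlled-access; it emulates their *structure* so the pipeline is
testable by parameter recovery, and it makes no claim to be a model of
drinking behavior. Defaults were chosen once to mirror the published
baseline table of the five-trial pool: per-study sizes 594/346/130/221/200
(total 1491), treatment lengths 16/26/16/12/13 weeks, a baseline risk
mixture of 4.4% medium / 18.0% high / 77.5% very-high (renormalized from
printed percentages), per-study DSLD means from 0.2 to 7.8 days, and
demographic marginals near the published pooled rates.

Daily drinking is a first-order two-state (drink/no-drink) Markov chain —
the simplest process that produces runs of abstinence, which DSLD needs —
with persistence 0.3 and stationary drinking-day probability by risk
stratum (0.55/0.70/0.85), and lognormal grams on drinking days (sdlog
0.5). Each participant's baseline-window mean is rescaled to a target drawn
uniformly within the assigned stratum's gram band, so the derived baseline
level equals the assigned stratum by construction and the mixture is exact
up to sampling noise. DSLD is induced by forcing a terminal abstinent run
of study-specific negative-binomial length (capped one day short of the
observed history) and forcing a drinking day immediately before it, which
keeps per-study DSLD means controllable and makes the derived DSLD equal
the drawn truth.

Outcomes follow a logistic link: a latent success indicator with
configurable intercept (−3.1), DSLD slope (0.15 per day), age slope (0.03
per year, centered at 45), arm effect (0.15), and baseline-stratum effects
(0 by default). Latent successes drink nothing during treatment;
everyone else gets a graded drinking reduction (a participation/placebo
response) correlated with the same linear predictor, tuned so the derived
outcome marginals sit near the published pooled rates (about 11% abstinent,
56% WHO 2+, 84% completers). Dropout is geometric with daily hazard 0.0015
applied to latent non-successes — dropout in these trials accompanies a
return to drinking — which yields roughly 14% non-completers and keeps the
abstinence endpoint identical to the latent truth, so coefficient recovery
is exact in expectation. A step-function DSLD effect can replace the linear
term for cutoff-recovery experiments.

What the generator does *not* emulate: within-day drinking patterns,
scattered mid-study missingness not caused by dropout, site-level
clustering, seasonal or weekly periodicity, and measurement error in
self-report. Passing recovery tests therefore demonstrates that the
pipeline computes its definitions correctly and recovers known effects
under a clean generative truth — not that those effects are estimable
without bias from real, messier TLFB data.

One implementation note: generation is vectorized across participants from
a single seeded stream, so a whole trial is reproducible from (config,
seed) but individual participants do not own RNG substreams; removing a
participant from the configuration changes the draws of the others. The
vectorization is what makes replicate-level recovery studies (hundreds of
trials of n = 5000) affordable on one CPU.

## Problem sizes used in the shipped checks

The packaged checks run at sizes chosen to give stable Monte Carlo
estimates while remaining quick on a laptop: oracle-equivalence sweeps use
a 0.1 g grid over 0–200 g/day and 1000 random instances; coefficient
recovery averages 100 replicate trials of n = 5000 (relative bias under
10%); Wald interval coverage uses 500 replicates at n = 2000 (coverage
within [0.90, 0.98]); cutoff recovery uses 200 replicates at n = 600 with
a step effect at 3 days (the 3.5-day midpoint is found in at least 90%).

## Known limitations

The package computes fixed-effects logistic screens only — no multiple
imputation, no mixed-effects site models, no interactions. The endpoint
layer implements one reading of "dropouts and missing data recoded to no
change" (any missing endpoint-window day voids the window); analyses of
real data should check sensitivity under `observed_only = TRUE`. The
gram-per-drink constant and heavy-day thresholds are conventions, not
universals, and should be set explicitly when a protocol differs.
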