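# tlfbtrials

Derivation of FDA-guided drinking endpoints from timeline follow-back
(TLFB) calendars, and predictor screening across harmonized multi-site
alcohol use disorder (AUD) pharmacotherapy trials.

## The problem

AUD medication trials measure efficacy from daily self-reported drinking
collected with the TLFB calendar. The daily records must be summarized into
regulatory endpoints before any modeling can happen, and the summarization
rules — assessment windows, worst-case imputation of unreported days,
sex-specific thresholds — are easy to get subtly wrong. `tlfbtrials`
implements that derivation as tested, reusable code for four binary
outcomes per participant:

- **Total abstinence** — zero drinks on every treatment day, with
  *worst-case imputation*: any unreported day counts as a return to
  drinking.
- **No heavy drinking days** — no day at or above 5 standard drinks (men)
  or 4 (women), same imputation.
- **WHO 2+ risk drinking level (RDL) reduction** — the WHO risk level over
  the final 28 treatment days sits at least two ordinal levels below the
  level over the 28 days before screening. Risk levels use the WHO gram/day
  bands (men: low ≤ 40 g, medium 40–60 g, high 60–100 g, very high > 100 g;
  women: 20/40/60 g), with abstinent as a fifth level below low, so a
  medium-risk baseline succeeds only via complete endpoint abstinence.
  Dropouts and missing endpoint windows are recoded to "no change".
- **Research completer** — TLFB data present on the final treatment day.

plus **DSLD** (days since last drink): the consecutive abstinent days
immediately before randomization, a strong predictor of all drinking
outcomes.

On top of the endpoints the package provides the analysis stage used to
screen trial-design predictors: logistic regression of each outcome on
baseline drinking and demographic covariates (controlling for study and
arm) with Wald tests and a Bonferroni threshold of α/m = 0.05/4 = 0.0125;
ROC curves with Youden's J = sensitivity + specificity − 1 to locate
operational DSLD cutoffs; and contingency/group-comparison tables
(chi-squared, t, ANOVA).

Because the source clinical datasets are controlled-access, the package
includes a synthetic multi-study trial generator with known truth — a
two-state Markov drinking process with lognormal grams, study-specific
DSLD distributions, configurable logistic outcome effects, and a dropout
process — so the whole pipeline is testable end to end by parameter
recovery.

## Worked example

```r
library(tlfbtrials)

cfg <- pipeline_config(input = simulation_config(), seed = 1)
res <- run_pipeline(cfg)

res$manifest$n_analysis
#> [1] 1491

round(100 * colMeans(res$analysis$table[, c("abstinent", "no_heavy",
                                            "who2plus", "completer")]), 1)
#> abstinent  no_heavy  who2plus completer
#>       9.5      10.1      52.9      84.1

co <- res$fits$abstinent.all$coefficients
co[co$term == "dsld", c("estimate", "std_error", "p_value")]
#> # A tibble: 1 x 3
#>   estimate std_error  p_value
#>      <dbl>     <dbl>    <dbl>
#> 1    0.147    0.0200 2.17e-13

res$rocs$who2plus
#> <roc_curve> AUC = 0.612; Youden's J maximized at cutoff 5.50 (J = 0.186); 789 positives / 702 negatives
```

The simulated pool mirrors the structure of five harmonized AUD trials
(1491 participants after excluding low-risk baselines). The `dsld`
coefficient is the log-odds increase in total abstinence per additional
pre-randomization abstinent day — here 0.147, close to the generator's
configured truth of 0.15, and significant far below the 0.0125 threshold.
The ROC summary says participants with roughly six or more abstinent days
before randomization are markedly more likely to meet the WHO 2+ reduction
endpoint, the kind of cutoff a trial designer would use as an inclusion
criterion to damp placebo response.

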