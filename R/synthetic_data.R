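# Synthetic multi-study AUD trial generator with known truth.
#
# Emulates the structure of the harmonized trial pool: per-participant daily
# drinking over a pre-screening month, a screening gap, and a 12-26 week
# treatment period; a baseline WHO RDL mixture skewed to very-high risk; a
# terminal pre-randomization abstinent run (DSLD) with study-specific
# distributions; treatment-period drinking modified by arm and covariate
# effects through a logistic link; and a dropout process after which all
# days are unreported.

default_study_table <- function() {
  tibble::tibble(
    study_name = c("combine", "horizant", "levetiracetam", "quetiapine",
                   "varenicline"),
    n = c(594L, 346L, 130L, 221L, 200L),
    treatment_weeks = c(16L, 26L, 16L, 12L, 13L),
    dsld_mean = c(7.8, 3.5, 0.6, 1.8, 0.2),
    dsld_sd = c(5.2, 1.5, 1.8, 4.2, 0.6),
    placebo_prop = c(0.254, 0.500, 0.508, 0.525, 0.505)
  )
}

default_demographics <- function() {
  list(
    male_prop = 0.704,
    age_mean = 45.9, age_sd = 10.9, age_range = c(18, 75),
    marital_probs = c("married" = 0.42, "cohabitating" = 0.05,
                      "separated" = 0.06, "divorced" = 0.22,
                      "widowed" = 0.02, "never married" = 0.23),
    employment_probs = c("full time" = 0.60, "part time" = 0.12,
                         "unemployed" = 0.12, "disabled" = 0.05,
                         "retired" = 0.06, "student" = 0.04,
                         "military" = 0.01),
    income_probs = c("<20k" = 0.15, "20-40k" = 0.20, "40-60k" = 0.185,
                     "60-80k" = 0.175, "80-100k" = 0.12, "100k+" = 0.17),
    education_years_probs = c("10" = 0.030, "11" = 0.024, "12" = 0.300,
                              "14" = 0.350, "16" = 0.296),
    cigarettes_probs = c("0" = 0.600, "5" = 0.138, "20" = 0.262),
    thc_positive_prop = 0.117,
    race_probs = c("white" = 0.780, "black" = 0.170, "mixed" = 0.035,
                   "native american" = 0.010, "asian/pacific islander" = 0.005),
    hispanic_prop = 0.078
  )
}

#' Configuration for the synthetic trial generator
#'
#' All generative parameters with their emulation-target defaults: per-study
#' sample sizes, treatment lengths and DSLD distributions mirroring the five
#' harmonized trials; a baseline WHO RDL mixture of 4.4% medium / 18.0% high
#' / 77.5% very-high risk; a two-state Markov drinking process with
#' lognormal grams on drinking days; a daily dropout hazard tuned to roughly
#' 14% non-completers; and logistic-scale outcome-model coefficients (DSLD,
#' age, arm, baseline RDL) whose truth is echoed into the output for
#' parameter-recovery tests.
#'
#' @param seed Integer seed; `simulate_trial()` is fully reproducible from
#'   (config, seed).
#' @param studies Per-study design tibble (`study_name`, `n`,
#'   `treatment_weeks`, `dsld_mean`, `dsld_sd`, `placebo_prop`).
#' @param n_total If given, per-study sizes are rescaled proportionally to
#'   this total.
#' @param rdl_mixture Baseline RDL mixture over medium/high/very_high; must
#'   sum to 1.
#' @param drink_day_prob Per-stratum stationary drinking-day probability.
#' @param markov_persistence Day-to-day persistence of the drink/no-drink
#'   state, in [0, 1).
#' @param grams_sdlog Lognormal sd (log scale) of grams on drinking days.
#' @param target_mean_ranges Per-sex, per-stratum gram/day ranges the
#'   baseline-window mean is drawn from.
#' @param screening_gap_days Days between the screening visit and
#'   randomization.
#' @param dropout_hazard Daily dropout hazard during treatment (applied to
#'   participants not on the latent-success trajectory, reflecting that
#'   dropout accompanies a return to drinking).
#' @param reduction Graded treatment-period drinking-reduction process
#'   (participation/placebo response): `offset` and `sd` on the logistic
#'   scale, `max` reduction fraction, and `grams_factor` scaling how much
#'   of the reduction hits per-occasion grams.
#' @param outcome_model List of logistic-scale coefficients: `intercept`,
#'   `beta_dsld`, `beta_age` (per year, centered at 45), `beta_arm_active`,
#'   `beta_high`, `beta_very_high`; optionally `dsld_step =
#'   list(threshold, logit_low, logit_high)` replacing the linear DSLD term
#'   with a step for cutoff-recovery experiments.
#' @param demographics Demographic marginals (see source for fields).
#' @param grams_per_drink Grams of ethanol per standard drink.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              studies = default_study_table(),
                              n_total = NULL,
                              rdl_mixture = c(medium = 0.044, high = 0.180,
                                              very_high = 0.775),
                              drink_day_prob = c(medium = 0.55, high = 0.70,
                                                 very_high = 0.85),
                              markov_persistence = 0.3,
                              grams_sdlog = 0.5,
                              target_mean_ranges = list(
                                male = list(medium = c(40, 60), high = c(60, 100),
                                            very_high = c(100, 250)),
                                female = list(medium = c(20, 40), high = c(40, 60),
                                              very_high = c(60, 150))),
                              screening_gap_days = 14L,
                              dropout_hazard = 0.0015,
                              reduction = list(offset = 3.0, sd = 1.5,
                                               max = 0.85, grams_factor = 0.7),
                              outcome_model = list(intercept = -3.1,
                                                   beta_dsld = 0.15,
                                                   beta_age = 0.03,
                                                   beta_arm_active = 0.15,
                                                   beta_high = 0,
                                                   beta_very_high = 0,
                                                   dsld_step = NULL),
                              demographics = default_demographics(),
                              grams_per_drink = 14.0) {
  if (!is.null(n_total)) {
    scaled <- pmax(1L, as.integer(round(studies$n * n_total / sum(studies$n))))
    studies$n <- scaled
  }
  # printed-percentage mixtures can miss 1 by rounding; renormalize
  if (abs(sum(rdl_mixture) - 1) > 0.02) stop("rdl_mixture must sum to 1")
  rdl_mixture <- rdl_mixture / sum(rdl_mixture)
  stopifnot(all(rdl_mixture >= 0),
            all(drink_day_prob > 0 & drink_day_prob <= 1),
            markov_persistence >= 0, markov_persistence < 1,
            dropout_hazard >= 0, dropout_hazard < 1,
            screening_gap_days >= 1, grams_per_drink > 0)
  structure(
    list(seed = as.integer(seed), studies = studies, rdl_mixture = rdl_mixture,
         drink_day_prob = drink_day_prob,
         markov_persistence = markov_persistence, grams_sdlog = grams_sdlog,
         target_mean_ranges = target_mean_ranges,
         screening_gap_days = as.integer(screening_gap_days),
         dropout_hazard = dropout_hazard, reduction = reduction,
         outcome_model = outcome_model,
         demographics = demographics, grams_per_drink = grams_per_drink),
    class = "simulation_config")
}

# First-order two-state Markov chain, vectorized over participants:
# stationary probability p (per participant), persistence phi.
markov_drink_matrix <- function(p, n_days, phi) {
  n <- length(p)
  D <- matrix(FALSE, n, n_days)
  if (n_days == 0L) return(D)
  D[, 1L] <- stats::runif(n) < p
  if (n_days > 1L) {
    p11 <- p + phi * (1 - p)
    p01 <- p * (1 - phi)
    for (j in 2:n_days) {
      pj <- p01 + (p11 - p01) * D[, j - 1L]
      D[, j] <- stats::runif(n) < pj
    }
  }
  D
}

draw_dsld <- function(mu, sd, n) {
  if (mu <= 0) return(integer(n))
  v <- sd^2
  if (v > mu * 1.0001) {
    size <- mu^2 / (v - mu)
    stats::rnbinom(n, size = size, mu = mu)
  } else {
    stats::rpois(n, mu)
  }
}

linear_predictor <- function(om, dsld, age, arm_active, stratum) {
  eta_dsld <- if (!is.null(om$dsld_step)) {
    st <- om$dsld_step
    st$logit_low + (st$logit_high - st$logit_low) * (dsld > st$threshold)
  } else {
    om$intercept + om$beta_dsld * dsld
  }
  eta_dsld + om$beta_age * (age - 45) + om$beta_arm_active * arm_active +
    om$beta_high * (stratum == "high") + om$beta_very_high * (stratum == "very_high")
}

# Core generator; assumes the RNG state has been set by the caller.
sim_core <- function(cfg, id_offset = 0L) {
  st <- cfg$studies
  n <- sum(st$n)
  study <- rep(st$study_name, st$n)
  end_day <- rep(st$treatment_weeks * 7L, st$n)
  dsld_mu <- rep(st$dsld_mean, st$n)
  dsld_sd <- rep(st$dsld_sd, st$n)
  placebo_p <- rep(st$placebo_prop, st$n)
  idx_within <- unlist(lapply(st$n, seq_len), use.names = FALSE)
  pid <- sprintf("%s-%05d", study, idx_within + id_offset)

  dm <- cfg$demographics
  sex <- ifelse(stats::runif(n) < dm$male_prop, "male", "female")
  age <- pmin(pmax(stats::rnorm(n, dm$age_mean, dm$age_sd), dm$age_range[1]),
              dm$age_range[2])
  arm <- ifelse(stats::runif(n) < placebo_p, "placebo", "active")
  marital <- sample(names(dm$marital_probs), n, TRUE, dm$marital_probs)
  employment <- sample(names(dm$employment_probs), n, TRUE, dm$employment_probs)
  income_band <- sample(names(dm$income_probs), n, TRUE, dm$income_probs)
  education_years <- as.numeric(
    sample(names(dm$education_years_probs), n, TRUE, dm$education_years_probs))
  cigarettes <- as.numeric(
    sample(names(dm$cigarettes_probs), n, TRUE, dm$cigarettes_probs))
  urine_thc <- ifelse(stats::runif(n) < dm$thc_positive_prop,
                      "positive", "negative")
  race <- sample(names(dm$race_probs), n, TRUE, dm$race_probs)
  hispanic <- stats::runif(n) < dm$hispanic_prop

  stratum <- sample(names(cfg$rdl_mixture), n, TRUE, cfg$rdl_mixture)
  combos <- expand.grid(sex = c("male", "female"),
                        stratum = names(cfg$rdl_mixture),
                        stringsAsFactors = FALSE)
  rng_tab <- t(mapply(function(s, st) cfg$target_mean_ranges[[s]][[st]],
                      combos$sex, combos$stratum))
  ci <- match(paste(sex, stratum), paste(combos$sex, combos$stratum))
  target_mean <- stats::runif(n, rng_tab[ci, 1], rng_tab[ci, 2])
  p_drink <- cfg$drink_day_prob[stratum]

  gap <- cfg$screening_gap_days
  screening_day <- -gap
  n_pre <- 28L + gap                      # days -(28+gap) .. -1
  pre_days <- seq.int(-n_pre, -1L)
  D <- markov_drink_matrix(p_drink, n_pre, cfg$markov_persistence)
  R <- matrix(0, n, n_pre)
  R[D] <- stats::rlnorm(sum(D), 0, cfg$grams_sdlog)

  # terminal abstinent run before randomization, study-specific length
  dsld <- integer(n)
  for (s in seq_len(nrow(st))) {
    rows <- study == st$study_name[s]
    dsld[rows] <- draw_dsld(st$dsld_mean[s], st$dsld_sd[s], sum(rows))
  }
  dsld <- pmin(dsld, n_pre - 1L)          # keep at least one drinkable day
  for (j in seq_len(n_pre)) {
    d <- pre_days[j]
    zero <- dsld >= -d                    # day inside the forced run
    R[zero, j] <- 0
    D[zero, j] <- FALSE
    force_drink <- dsld == (-d - 1L)      # day immediately before the run
    newly <- force_drink & !D[, j]
    if (any(newly)) R[newly, j] <- stats::rlnorm(sum(newly), 0, cfg$grams_sdlog)
    D[force_drink, j] <- TRUE
  }

  # rescale the baseline window so its 28-day mean equals the drawn target,
  # guaranteeing the assigned baseline stratum
  win <- seq_len(28L)                     # days -(28+gap) .. -(gap+1)
  sumR <- rowSums(R[, win, drop = FALSE])
  dead <- sumR == 0
  if (any(dead)) {                        # Markov chance of an all-zero window
    R[dead, 1L] <- 1
    D[dead, 1L] <- TRUE
    sumR[dead] <- 1
  }
  scale <- target_mean * 28 / sumR
  R <- R * scale

  om <- cfg$outcome_model
  eta <- linear_predictor(om, dsld, age, arm == "active", stratum)
  latent_success <- stats::runif(n) < stats::plogis(eta)
  # graded drinking reduction during treatment (participation/placebo
  # response), correlated with the same linear predictor
  rd <- cfg$reduction
  rho <- rd$max * stats::plogis(eta + rd$offset + stats::rnorm(n, 0, rd$sd))

  n_treat <- max(end_day) + 1L            # days 0 .. max end
  Dt <- markov_drink_matrix(p_drink * (1 - rho), n_treat, cfg$markov_persistence)
  grams_per_dday <- target_mean / p_drink # baseline grams per drinking day
  meanlog <- log(grams_per_dday * (1 - rd$grams_factor * rho)) -
    cfg$grams_sdlog^2 / 2
  Rt <- matrix(0, n, n_treat)
  ml <- matrix(meanlog, n, n_treat)
  Rt[Dt] <- stats::rlnorm(sum(Dt), ml[Dt], cfg$grams_sdlog)
  Rt[latent_success, ] <- 0

  dropday <- rep(Inf, n)
  if (cfg$dropout_hazard > 0) {
    cand <- 1L + stats::rgeom(n, cfg$dropout_hazard)
    dropday[!latent_success] <- cand[!latent_success]
  }

  gpd <- cfg$grams_per_drink
  all_days <- c(pre_days, seq.int(0L, max(end_day)))
  n_cols <- length(all_days)
  drinks <- cbind(R, Rt) / gpd
  day_mat <- matrix(all_days, n, n_cols, byrow = TRUE)
  in_span <- day_mat <= end_day           # per-study calendar end
  miss <- day_mat >= dropday
  drinks[miss] <- NA_real_

  # transpose so column-major subsetting yields participant-major rows
  pid_mat <- matrix(pid, n, n_cols)
  keep <- t(in_span)
  tlfb <- tibble::tibble(
    participant_id = t(pid_mat)[keep],
    day = t(day_mat)[keep],
    drinks = t(drinks)[keep],
    missing = t(miss)[keep]
  )

  baseline <- tibble::tibble(
    participant_id = pid, study = study, arm = arm, sex = sex, age = age,
    marital = marital, employment = employment, income_band = income_band,
    education_years = education_years, cigarettes_per_day = cigarettes,
    urine_thc = urine_thc, race = race, hispanic = hispanic,
    screening_day = screening_day, treatment_end_day = end_day
  )
  truth <- list(
    config = cfg,
    participants = tibble::tibble(
      participant_id = pid, study = study, stratum = stratum,
      target_mean_grams = target_mean, dsld = dsld, eta = eta,
      latent_success = latent_success, rho = rho,
      dropout_day = ifelse(is.finite(dropday), dropday, NA_real_)
    )
  )
  list(baseline = baseline, tlfb = tlfb, truth = truth)
}

#' Simulate a full multi-study trial
#'
#' Generates the raw baseline table and long-format TLFB table in exactly
#' the dialects the pipeline reads, plus a truth record holding every
#' generative parameter and per-participant latent state for
#' parameter-recovery tests. Fully reproducible from (config, seed).
#'
#' @param cfg A [simulation_config()].
#' @return List: `baseline` (raw per-study baseline tibble including
#'   `screening_day` and `treatment_end_day` anchors), `tlfb` (long daily
#'   records), `truth`.
#' @export
simulate_trial <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  sim_core(cfg)
}

#' Simulate a single participant
#'
#' Convenience wrapper around the trial generator for one participant of
#' one study; returns the raw baseline row and a [tlfb_calendar()].
#'
#' @param cfg A [simulation_config()].
#' @param study Study name (must appear in `cfg$studies`).
#' @param seed Seed for this participant's draw (defaults to `cfg$seed`).
#' @return List: `baseline` (one-row tibble), `calendar`.
#' @export
simulate_participant <- function(cfg = simulation_config(), study = "combine",
                                 seed = cfg$seed) {
  row <- cfg$studies[cfg$studies$study_name == study, ]
  if (nrow(row) != 1L) stop("unknown study: ", study)
  row$n <- 1L
  cfg1 <- cfg
  cfg1$studies <- row
  set.seed(seed)
  sim <- sim_core(cfg1)
  cal <- tlfb_calendar(sim$baseline$participant_id[1], sim$tlfb[, -1],
                       screening_day = sim$baseline$screening_day[1],
                       treatment_end_day = sim$baseline$treatment_end_day[1])
  list(baseline = sim$baseline, calendar = cal, truth = sim$truth)
}

#' Simulate harmonized covariates and a logistic outcome directly
#'
#' Lightweight generator that skips the daily calendars: draws the
#' harmonized covariate set (study, arm, baseline RDL, DSLD, age,
#' demographics) from the configured marginals and one binary outcome from
#' the configured logistic link. Used for interval-coverage and
#' cutoff-recovery experiments where only the regression truth matters.
#'
#' @param cfg A [simulation_config()].
#' @param n Number of rows.
#' @param outcome Name of the outcome column to create.
#' @return Tibble in analysis-table layout with attribute `"eta"` (true
#'   linear predictor).
#' @export
simulate_logistic_outcomes <- function(cfg = simulation_config(), n = 2000L,
                                       outcome = "abstinent") {
  st <- cfg$studies
  dm <- cfg$demographics
  si <- sample(nrow(st), n, TRUE, prob = st$n)
  dsld <- integer(n)
  for (s in unique(si)) {
    rows <- si == s
    dsld[rows] <- draw_dsld(st$dsld_mean[s], st$dsld_sd[s], sum(rows))
  }
  dsld <- pmin(dsld, 27L + cfg$screening_gap_days)
  age <- pmin(pmax(stats::rnorm(n, dm$age_mean, dm$age_sd), dm$age_range[1]),
              dm$age_range[2])
  arm <- ifelse(stats::runif(n) < st$placebo_prop[si], "placebo", "active")
  stratum <- sample(names(cfg$rdl_mixture), n, TRUE, cfg$rdl_mixture)
  eta <- linear_predictor(cfg$outcome_model, dsld, age, arm == "active", stratum)
  out <- tibble::tibble(
    participant_id = sprintf("p%05d", seq_len(n)),
    study = st$study_name[si], arm = arm,
    sex = ifelse(stats::runif(n) < dm$male_prop, "male", "female"),
    age = age,
    married_cohab = stats::runif(n) < 0.47,
    employed = stats::runif(n) < 0.72,
    income_60k = stats::runif(n) < 0.46,
    education_12plus = stats::runif(n) < 0.95,
    smoker_10plus = stats::runif(n) < 0.26,
    thc_positive = stats::runif(n) < dm$thc_positive_prop,
    race_white = stats::runif(n) < 0.75,
    race_black = stats::runif(n) < 0.16,
    race_hispanic = stats::runif(n) < dm$hispanic_prop,
    baseline_rdl = rdl_factor(stratum),
    dsld = dsld
  )
  out[[outcome]] <- stats::runif(n) < stats::plogis(eta)
  attr(out, "eta") <- eta
  out
}
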