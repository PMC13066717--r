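test_that("Bonferroni threshold is plain division", {
  expect_identical(bonferroni_threshold(0.05, 4), 0.0125)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.01, 5), 0.002)
  expect_identical(bonferroni_threshold(0.05, 4) * 4, 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
})

constant_table <- function(n, y) {
  tibble::tibble(
    participant_id = sprintf("p%d", seq_len(n)),
    study = "combine", arm = "placebo", sex = "male", age = 45,
    married_cohab = TRUE, employed = TRUE, income_60k = TRUE,
    education_12plus = TRUE, smoker_10plus = FALSE, thc_positive = FALSE,
    race_white = TRUE, race_black = FALSE, race_hispanic = FALSE,
    baseline_rdl = rdl_factor(rep("very_high", n)), dsld = 0L,
    abstinent = y
  )
}

test_that("logistic fit handles degenerate designs honestly", {
  # balanced outcome, all predictors constant: intercept-only, logit(0.5) = 0
  tab <- constant_table(200, rep(c(TRUE, FALSE), 100))
  fit <- fit_outcome_model(tab, "abstinent")
  expect_equal(nrow(fit$coefficients), 1L)
  expect_lt(abs(fit$coefficients$estimate[1]), 1e-8)
  # one-class outcome refuses to fit
  expect_error(fit_outcome_model(constant_table(50, rep(TRUE, 50)), "abstinent"),
               "single-class")
})

test_that("logistic fit recovers a known DSLD effect", {
  cfg <- simulation_config(seed = 5)
  set.seed(501)
  tab <- simulate_logistic_outcomes(cfg, n = 5000)
  fit <- fit_outcome_model(tab, "abstinent")
  est <- fit$coefficients$estimate[fit$coefficients$term == "dsld"]
  expect_lt(abs(est - cfg$outcome_model$beta_dsld), 0.05)
  expect_true(fit$converged)
  # medium risk is the reference: no 'medium' coefficient, two RDL terms
  expect_length(grep("^baseline_rdl", fit$coefficients$term), 2L)
  expect_false(any(grepl("medium", fit$coefficients$term)))
  # placebo-only subset drops the arm term
  set.seed(502)
  fit2 <- fit_outcome_model(simulate_logistic_outcomes(cfg, n = 3000),
                            "abstinent", subset = "placebo_only")
  expect_false(any(grepl("^arm", fit2$coefficients$term)))
  expect_lt(fit2$n_used, 3000)
  # block LR tests cover the two multi-level categorical predictors
  expect_setequal(fit$block_tests$term, c("study", "baseline_rdl"))
  expect_true(all(fit$block_tests$p_value >= 0 & fit$block_tests$p_value <= 1))
})

test_that("ROC/Youden finds the separating threshold and honours ties", {
  # perfect separation
  r <- roc_youden(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(r$optimal_cutoff, 6.5)
  expect_equal(r$optimal_youden, 1)
  expect_equal(r$auc, 1)
  # independence: AUC near 1/2
  set.seed(41)
  r2 <- roc_youden(stats::rnorm(4000), stats::runif(4000) < 0.4)
  expect_lt(abs(r2$auc - 0.5), 0.03)
  # 8-point toy set against exhaustive search
  x <- c(0, 1, 1, 2, 3, 3, 4, 5); y <- c(F, F, T, F, T, T, T, T)
  r3 <- roc_youden(x, y)
  o <- oracle_youden_cutoff(x, y)
  expect_equal(r3$optimal_cutoff, o$cutoff)
  expect_equal(r3$optimal_youden, o$J)
  # integer predictors give half-integer cutoffs
  expect_true(r3$optimal_cutoff %% 1 == 0.5)
  expect_error(roc_youden(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("ROC cutoffs match exhaustive search and AUC its trapezoid", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    x <- sample(0:20, n, replace = TRUE)
    y <- stats::runif(n) < stats::plogis(-1 + 0.2 * x)
    if (!any(y) || all(y)) next
    r <- roc_youden(x, y)
    o <- oracle_youden_cutoff(x, y)
    expect_equal(r$optimal_cutoff, o$cutoff)
    expect_equal(r$optimal_youden, o$J, tolerance = 1e-12)
    # AUC identity with the coordinate table
    fpr <- 1 - r$coords$specificity
    ord <- order(fpr, r$coords$sensitivity)
    tr <- sum(diff(fpr[ord]) *
                (r$coords$sensitivity[ord][-1] +
                   utils::head(r$coords$sensitivity[ord], -1)) / 2)
    expect_equal(r$auc, tr)
  }
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  x <- sample(0:15, 500, replace = TRUE)
  y <- stats::runif(500) < stats::plogis(-2 + 0.25 * x)
  r <- roc_youden(x, y)
  pr <- pROC::roc(response = y, predictor = x, quiet = TRUE,
                  direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  best <- pROC::coords(pr, "best", best.method = "youden")
  expect_equal(r$optimal_cutoff, as.numeric(best$threshold[1]))
})

test_that("cutoff contingency tables count, percentage and test correctly", {
  # no association: chi-squared exactly zero
  tab0 <- dplyr::bind_rows(expand_counts(20, 10, 1, "abstinent"),
                           expand_counts(20, 10, 5, "abstinent"))
  ct0 <- cutoff_table(tab0, 3.5, outcomes = "abstinent")
  expect_equal(ct0$chisq, 0)
  expect_equal(ct0$p_value, 1)
  # closed-form oracle on an unbalanced toy table
  tab1 <- dplyr::bind_rows(expand_counts(20, 5, 1, "abstinent"),
                           expand_counts(20, 15, 5, "abstinent"))
  ct1 <- cutoff_table(tab1, 3.5, outcomes = "abstinent")
  expect_equal(ct1$chisq, oracle_chisq_2x2(rbind(c(5, 15), c(15, 5))))
  expect_equal(ct1$pct_low, 25)
  expect_equal(ct1$pct_high, 75)
  expect_error(cutoff_table(tab1, 99), "outside")
})

test_that("chi-squared association is invariant to table permutation", {
  set.seed(44)
  for (i in 1:50) {
    m <- matrix(sample(5:60, 4), 2)
    a <- suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic
    b <- suppressWarnings(stats::chisq.test(m[2:1, 2:1], correct = FALSE))$statistic
    expect_equal(oracle_chisq_2x2(m), unname(a), tolerance = 1e-12)
    expect_equal(unname(a), unname(b))
  }
})

test_that("group comparisons pick the right test and match closed forms", {
  # identical groups: t = 0, p = 1
  d <- tibble::tibble(g = rep(c(TRUE, FALSE), each = 5),
                      x = rep(c(1, 2, 3, 4, 5), 2))
  r <- group_compare(d, "x", "g", "continuous")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$test, "t")
  # 3-group ANOVA equals the direct sum-of-squares F
  set.seed(45)
  g <- rep(c("a", "b", "c"), each = 30)
  x <- stats::rnorm(90, mean = rep(c(0, 0.5, 1), each = 30))
  r3 <- group_compare(tibble::tibble(g = g, x = x), "x", "g", "continuous")
  grand <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 87)
  expect_equal(r3$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(r3$test, "anova")
  # pooled vs Welch both available
  d2 <- tibble::tibble(g = rep(c(TRUE, FALSE), c(40, 20)),
                       x = c(stats::rnorm(40, 0, 1), stats::rnorm(20, 1, 3)))
  tp <- group_compare(d2, "x", "g", "continuous", welch = FALSE)
  tw <- group_compare(d2, "x", "g", "continuous", welch = TRUE)
  expect_false(isTRUE(all.equal(tp$statistic, tw$statistic)))
  # categorical route
  d3 <- tibble::tibble(g = rep(c("x", "y"), each = 50),
                       v = rep(c("a", "b", "a", "a"), length.out = 100))
  rc <- group_compare(d3, "v", "g", "categorical")
  expect_equal(rc$test, "chisq")
  expect_true(rc$p_value >= 0 && rc$p_value <= 1)
})

test_that("outcome rates by baseline risk level tabulate correctly", {
  tab <- tibble::tibble(
    baseline_rdl = rdl_factor(rep(c("medium", "high", "very_high"),
                                  c(10, 20, 70))),
    abstinent = rep(c(TRUE, FALSE), c(5, 95))
  )
  rt <- rdl_outcome_table(tab, outcomes = "abstinent")
  med <- rt[rt$baseline_rdl == "medium", ]
  expect_equal(med$n, 10)
  expect_equal(med$k, 5)
  expect_equal(med$pct, 50)
})
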