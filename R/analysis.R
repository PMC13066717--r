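# Statistical stage: logistic predictor models with Bonferroni gating,
# ROC/Youden cutoff discovery, contingency tables and group comparisons.

outcome_labels <- function() c("abstinent", "no_heavy", "who2plus", "completer")

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Familywise error rate, in (0, 1).
#' @param m Number of tests (here, the four modeled outcomes).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 4L) {
  stopifnot(length(alpha) == 1L, length(m) == 1L)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be a positive integer")
  alpha / m
}

model_predictors <- function(subset) {
  preds <- c("study", "arm", "baseline_rdl", "dsld", "age", "smoker_10plus",
             "thc_positive", "sex", "employed", "education_12plus",
             "married_cohab", "income_60k", "race_white", "race_black",
             "race_hispanic")
  if (subset == "placebo_only") preds <- setdiff(preds, "arm")
  preds
}

#' Fit a logistic predictor-screening model for one outcome
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of one
#' binary outcome on the harmonized predictor set: study, placebo vs active
#' arm (omitted in the placebo-only subset), baseline WHO RDL with medium
#' risk as the reference level, days since last drink, age, smoking, THC,
#' sex, employment, education, marital status, income and the three race
#' indicators. Per-coefficient Wald tests; a single likelihood-ratio p-value
#' per multi-level categorical block (study, baseline RDL). Fits are
#' complete-case over the model columns, with the dropped count logged.
#'
#' @param table Analysis tibble (see [build_analysis_table()]).
#' @param outcome One of `"abstinent"`, `"no_heavy"`, `"who2plus"`,
#'   `"completer"`.
#' @param subset `"all"` or `"placebo_only"`.
#' @param sig_threshold Significance threshold for flagging (default the
#'   Bonferroni 0.05/4 = 0.0125).
#' @param block_tests Compute the likelihood-ratio block tests for the
#'   multi-level categorical predictors (two extra model fits); disable in
#'   tight simulation loops that only need the coefficients.
#' @return A `logistic_fit` list: `outcome`, `subset`, `coefficients`
#'   (tibble of term, estimate, std_error, statistic, p_value, significant),
#'   `block_tests` (likelihood-ratio p per categorical block), `converged`,
#'   `n_used`, `n_dropped`, `reference_levels`.
#' @export
fit_outcome_model <- function(table, outcome = outcome_labels(),
                              subset = c("all", "placebo_only"),
                              sig_threshold = bonferroni_threshold(0.05, 4),
                              block_tests = TRUE) {
  outcome <- match.arg(outcome)
  subset <- match.arg(subset)
  dat <- tibble::as_tibble(table)
  if (subset == "placebo_only") dat <- dat[dat$arm == "placebo", ]
  preds <- intersect(model_predictors(subset), names(dat))
  need <- setdiff(model_predictors(subset), names(dat))
  if (length(need)) stop("analysis table lacks predictors: ",
                         paste(need, collapse = ", "))
  dat <- dat[, c(outcome, preds)]
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, ]
  y <- dat[[outcome]]
  if (length(unique(y)) < 2L) {
    stop(sprintf("outcome '%s' is single-class in this subset; model not identifiable",
                 outcome))
  }
  # medium risk is the reference for the baseline RDL block
  dat$baseline_rdl <- stats::relevel(
    factor(as.character(dat$baseline_rdl),
           levels = c("medium", "high", "very_high")), ref = "medium")
  dat$study <- factor(dat$study)
  if ("arm" %in% preds) {
    dat$arm <- factor(dat$arm)
    if ("active" %in% levels(dat$arm)) dat$arm <- stats::relevel(dat$arm, "active")
  }
  dat$sex <- factor(dat$sex, levels = c("female", "male"))
  # drop constant predictors (e.g. single-study tables) rather than fail
  keep <- vapply(preds, function(p) length(unique(dat[[p]])) > 1L, TRUE)
  preds_used <- preds[keep]
  rhs <- if (length(preds_used)) paste(preds_used, collapse = " + ") else "1"
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::glm(form, data = dat, family = stats::binomial())
  sm <- summary(fit)
  co <- sm$coefficients
  separation <- any(abs(co[, "Estimate"]) > 15 & co[, "Std. Error"] > 100)
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "z value"],
    p_value = co[, "Pr(>|z|)"]
  )
  coefs$significant <- coefs$p_value < sig_threshold
  blocks <- if (block_tests) intersect(c("study", "baseline_rdl"), preds_used)
            else character()
  block_res <- dplyr::bind_rows(lapply(blocks, function(b) {
    reduced <- stats::update(fit, stats::as.formula(paste(". ~ . -", b)))
    lrt <- stats::anova(reduced, fit, test = "LRT")
    tibble::tibble(term = b, df = lrt$Df[2], deviance = lrt$Deviance[2],
                   p_value = lrt$`Pr(>Chi)`[2],
                   significant = lrt$`Pr(>Chi)`[2] < sig_threshold)
  }))
  structure(
    list(outcome = outcome, subset = subset, coefficients = coefs,
         block_tests = block_res,
         converged = fit$converged && !separation,
         n_used = nrow(dat), n_dropped = n_dropped,
         sig_threshold = sig_threshold,
         reference_levels = list(baseline_rdl = "medium",
                                 arm = if ("arm" %in% preds_used) "active" else NULL,
                                 sex = "female"),
         glm = fit),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> outcome '%s' (%s subset), n = %d (%d dropped), %s\n",
              x$outcome, x$subset, x$n_used, x$n_dropped,
              if (x$converged) "converged" else "NOT CONVERGED / separated"))
  print(as.data.frame(x$coefficients), digits = 3)
  if (nrow(x$block_tests)) {
    cat("Categorical block likelihood-ratio tests:\n")
    print(as.data.frame(x$block_tests), digits = 3)
  }
  invisible(x)
}

#' ROC curve with Youden's index and the optimal cutoff
#'
#' Evaluates every achievable threshold -- the midpoints between consecutive
#' distinct predictor values, plus minus/plus infinity -- classifying
#' "positive" when the predictor exceeds the threshold. For an integer
#' predictor such as days since last drink this yields half-integer
#' candidate cutoffs. Youden's J = sensitivity + specificity - 1 is computed
#' at each threshold; the optimal cutoff maximizes J, ties broken toward the
#' smallest threshold. AUC is the trapezoidal area under the (1 -
#' specificity, sensitivity) curve.
#'
#' @param predictor Numeric vector.
#' @param outcome Logical (or 0/1) vector; both classes must be present.
#' @return A `roc_curve` list: `coords` (tibble of threshold, sensitivity,
#'   specificity, youden), `auc`, `optimal_cutoff`, `optimal_youden`, `n_pos`,
#'   `n_neg`.
#' @export
roc_youden <- function(predictor, outcome) {
  stopifnot(length(predictor) == length(outcome))
  outcome <- as.logical(outcome)
  ok <- !is.na(predictor) & !is.na(outcome)
  predictor <- predictor[ok]; outcome <- outcome[ok]
  if (!any(outcome) || all(outcome)) {
    stop("both outcome classes must be present for ROC analysis")
  }
  v <- sort(unique(predictor))
  thr <- c(-Inf, if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2, Inf)
  pos <- predictor[outcome]
  neg <- predictor[!outcome]
  sens <- vapply(thr, function(t) mean(pos > t), 0)
  spec <- vapply(thr, function(t) mean(neg <= t), 0)
  j <- sens + spec - 1
  coords <- tibble::tibble(threshold = thr, sensitivity = sens,
                           specificity = spec, youden = j)
  best <- which(j == max(j))[1L]  # thresholds ascending: first max = smallest
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  structure(
    list(coords = coords, auc = auc, optimal_cutoff = thr[best],
         optimal_youden = j[best], n_pos = length(pos), n_neg = length(neg)),
    class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f; Youden's J maximized at cutoff %.2f (J = %.3f); %d positives / %d negatives\n",
              x$auc, x$optimal_cutoff, x$optimal_youden, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  co <- x$coords[order(1 - x$coords$specificity, x$coords$sensitivity), ]
  plot(1 - co$specificity, co$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2)
  best <- which.min(abs(x$coords$threshold - x$optimal_cutoff))
  graphics::points(1 - x$coords$specificity[best], x$coords$sensitivity[best],
                   pch = 8, col = 2)
  invisible(x)
}

#' Outcome attainment split at a predictor cutoff
#'
#' For each binary outcome, counts and percentages of participants meeting
#' the outcome in the groups at-or-below vs above a predictor cutoff (e.g.
#' days since last drink split at 3.5 days), with a Pearson chi-squared test
#' of association (no continuity correction) flagged at the Bonferroni
#' threshold.
#'
#' @param table Analysis tibble.
#' @param cutoff Numeric cutoff on `predictor`.
#' @param predictor Column split on (default `"dsld"`).
#' @param outcomes Outcome columns to tabulate.
#' @param sig_threshold Significance flag threshold (default 0.0125).
#' @return A tibble: one row per outcome with group sizes `n_low`/`n_high`,
#'   success counts `k_low`/`k_high`, percentages `pct_low`/`pct_high`,
#'   `chisq`, `p_value`, `significant`.
#' @export
cutoff_table <- function(table, cutoff, predictor = "dsld",
                         outcomes = outcome_labels(),
                         sig_threshold = bonferroni_threshold(0.05, 4)) {
  x <- table[[predictor]]
  stopifnot(!is.null(x))
  if (cutoff < min(x, na.rm = TRUE) || cutoff > max(x, na.rm = TRUE)) {
    stop("cutoff outside the observed predictor range")
  }
  grp_low <- x <= cutoff
  rows <- lapply(outcomes, function(oc) {
    y <- as.logical(table[[oc]])
    n_low <- sum(grp_low); n_high <- sum(!grp_low)
    k_low <- sum(y[grp_low]); k_high <- sum(y[!grp_low])
    flagged <- n_low == 0L || n_high == 0L
    if (!flagged && length(unique(y)) > 1L) {
      ct <- suppressWarnings(
        stats::chisq.test(rbind(c(k_low, n_low - k_low),
                                c(k_high, n_high - k_high)), correct = FALSE))
      stat <- unname(ct$statistic); p <- ct$p.value
    } else {
      stat <- NA_real_; p <- NA_real_
    }
    tibble::tibble(outcome = oc, n_low = n_low, k_low = k_low,
                   pct_low = 100 * k_low / n_low,
                   n_high = n_high, k_high = k_high,
                   pct_high = 100 * k_high / n_high,
                   chisq = stat, p_value = p,
                   significant = !is.na(p) & p < sig_threshold,
                   flagged_empty_group = flagged)
  })
  dplyr::bind_rows(rows)
}

#' Outcome attainment by baseline risk drinking level
#'
#' Counts and percentages of participants meeting each outcome within each
#' baseline WHO RDL stratum, with a chi-squared test of association per
#' outcome.
#'
#' @param table Analysis tibble with `baseline_rdl` and outcome columns.
#' @param outcomes Outcome columns to tabulate.
#' @return Tibble: one row per (baseline level, outcome) with `n`, `k`,
#'   `pct`, plus per-outcome chi-squared `p_value`.
#' @export
rdl_outcome_table <- function(table, outcomes = outcome_labels()) {
  lev <- factor(as.character(table$baseline_rdl),
                levels = intersect(rdl_levels(), unique(as.character(table$baseline_rdl))))
  rows <- lapply(outcomes, function(oc) {
    y <- as.logical(table[[oc]])
    agg <- tapply(y, lev, function(v) c(n = length(v), k = sum(v)))
    p <- if (nlevels(lev) > 1L && length(unique(y)) > 1L) {
      suppressWarnings(stats::chisq.test(table(lev, y), correct = FALSE))$p.value
    } else NA_real_
    dplyr::bind_rows(lapply(names(agg), function(g) {
      tibble::tibble(baseline_rdl = g, outcome = oc,
                     n = unname(agg[[g]]["n"]), k = unname(agg[[g]]["k"]),
                     pct = unname(100 * agg[[g]]["k"] / agg[[g]]["n"]),
                     p_value = p)
    }))
  })
  dplyr::bind_rows(rows)
}

#' Compare a variable across outcome groups
#'
#' Continuous variables: pooled-variance two-sample t-test when the grouping
#' has two levels (`welch = TRUE` switches to Welch), one-way ANOVA for
#' three or more. Categorical variables: Pearson chi-squared without
#' continuity correction. Group means and SDs (or counts) are reported
#' alongside the test.
#'
#' @param table Data frame.
#' @param variable Column being compared.
#' @param grouping Grouping column (e.g. an outcome label or `study`).
#' @param type `"continuous"` or `"categorical"`.
#' @param welch Use Welch's t for two-group continuous comparisons.
#' @return List: `test` (`"t"`, `"anova"` or `"chisq"`), `statistic`,
#'   `p_value`, `groups` (tibble of per-group summaries), `flagged` (TRUE
#'   when a degenerate group prevented the test).
#' @export
group_compare <- function(table, variable, grouping,
                          type = c("continuous", "categorical"),
                          welch = FALSE) {
  type <- match.arg(type)
  g <- factor(table[[grouping]])
  x <- table[[variable]]
  if (nlevels(droplevels(g)) < 2L) stop("need at least two groups")
  if (type == "continuous") {
    x <- as.numeric(x)
    sums <- tibble::tibble(
      group = levels(g),
      n = as.integer(tapply(x, g, length)),
      mean = as.numeric(tapply(x, g, mean)),
      sd = as.numeric(tapply(x, g, stats::sd)))
    if (nlevels(g) == 2L) {
      if (all(sums$sd == 0, na.rm = TRUE)) {
        zero_diff <- diff(sums$mean) == 0
        return(list(test = "t", statistic = if (zero_diff) 0 else NA_real_,
                    p_value = if (zero_diff) 1 else NA_real_,
                    groups = sums, flagged = !zero_diff))
      }
      tt <- stats::t.test(x ~ g, var.equal = !welch)
      list(test = "t", statistic = unname(tt$statistic), p_value = tt$p.value,
           df = unname(tt$parameter), groups = sums, flagged = FALSE)
    } else {
      if (stats::var(x) == 0) {
        return(list(test = "anova", statistic = 0, p_value = 1,
                    groups = sums, flagged = TRUE))
      }
      av <- summary(stats::aov(x ~ g))[[1]]
      list(test = "anova", statistic = av[1, "F value"],
           p_value = av[1, "Pr(>F)"],
           df = c(av[1, "Df"], av[2, "Df"]), groups = sums, flagged = FALSE)
    }
  } else {
    tab <- table(g, factor(x))
    if (ncol(tab) < 2L) {
      return(list(test = "chisq", statistic = 0, p_value = 1,
                  groups = tibble::as_tibble(as.data.frame(tab)), flagged = TRUE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test = "chisq", statistic = unname(ct$statistic), p_value = ct$p.value,
         df = unname(ct$parameter),
         groups = tibble::as_tibble(as.data.frame(tab)), flagged = FALSE)
  }
}
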