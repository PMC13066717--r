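# Fixture builders and independent oracles shared across the suite.

# Calendar with explicit daily drinks; NA drinks mark missing days, and any
# day in drop_days is removed entirely (a reporting gap).
make_calendar <- function(drinks_by_day, screening_day = -14L,
                          treatment_end_day = NULL, id = "p1",
                          drop_days = integer()) {
  days <- as.integer(names(drinks_by_day))
  stopifnot(!is.null(days), !anyNA(days))
  tb <- tibble::tibble(
    day = days,
    drinks = as.numeric(drinks_by_day),
    missing = is.na(drinks_by_day)
  )
  tb <- tb[!tb$day %in% drop_days, ]
  if (is.null(treatment_end_day)) treatment_end_day <- max(days)
  tlfb_calendar(id, tb, screening_day, treatment_end_day)
}

# Dense calendar: full coverage from screening-28 to treatment_end with a
# constant drinks value, then point overrides.
dense_calendar <- function(screening_day = -14L, treatment_end_day = 28L,
                           fill = 0, overrides = numeric(), id = "p1",
                           drop_days = integer()) {
  days <- seq.int(screening_day - 28L, treatment_end_day)
  drinks <- rep(fill, length(days))
  names(drinks) <- days
  if (length(overrides)) drinks[names(overrides)] <- overrides
  make_calendar(drinks, screening_day, treatment_end_day, id, drop_days)
}

# Random small calendar for property tests: random drinking, random missing
# days, random gaps.
random_calendar <- function(id = "r1") {
  screening <- -sample(7:21, 1)
  end <- 7L * sample(4:12, 1)
  days <- seq.int(screening - 28L, end)
  drinks <- stats::rpois(length(days), lambda = sample(c(0.3, 1, 3), 1))
  miss <- stats::runif(length(days)) < 0.08
  drinks[miss] <- NA
  keep <- stats::runif(length(days)) > 0.05
  tb <- tibble::tibble(day = days, drinks = as.numeric(drinks),
                       missing = miss)[keep, ]
  tlfb_calendar(id, tb, screening, end)
}

# Backward-scan oracle for days since last drink: literal walk from day -1.
oracle_dsld <- function(cal) {
  lookup <- cal$days
  d <- -1L
  n <- 0L
  repeat {
    row <- lookup[lookup$day == d, ]
    if (nrow(row) != 1L) break
    if (row$missing || row$drinks > 0) break
    n <- n + 1L
    d <- d - 1L
  }
  n
}

# Interval-lookup oracle for the WHO RDL bands, via findInterval on the
# sex-specific cutpoints (right-closed bands).
oracle_rdl <- function(mean_grams, any_day, sex) {
  if (!any_day) return("abstinent")
  cuts <- if (sex == "male") c(40, 60, 100) else c(20, 40, 60)
  idx <- findInterval(mean_grams, cuts, left.open = TRUE) + 1L
  c("low", "medium", "high", "very_high")[idx]
}

# Exhaustive Youden-maximization oracle: evaluate J by direct counting at
# every midpoint threshold (and the two infinite ends), pick the smallest
# threshold attaining the maximum.
oracle_youden_cutoff <- function(x, y) {
  y <- as.logical(y)
  v <- sort(unique(x))
  thr <- c(-Inf, if (length(v) > 1) (utils::head(v, -1) + v[-1]) / 2, Inf)
  J <- sapply(thr, function(t) {
    sens <- sum(x > t & y) / sum(y)
    spec <- sum(x <= t & !y) / sum(!y)
    sens + spec - 1
  })
  list(cutoff = thr[which.max(J)], J = max(J))
}

# Closed-form Pearson chi-squared for a 2x2 table of counts.
oracle_chisq_2x2 <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Expand outcome counts into a participant-level tibble (for rebuilding
# published contingency tables as data).
expand_counts <- function(n, k, dsld_value, outcome) {
  tibble::tibble(
    dsld = rep(dsld_value, n),
    value = rep(c(TRUE, FALSE), c(k, n - k))
  ) |> stats::setNames(c("dsld", outcome))
}

# Small simulated trial plus per-participant calendars, for comparing the
# vectorized derivation against the per-calendar operations.
sim_with_calendars <- function(seed = 404, n_total = 60) {
  cfg <- simulation_config(seed = seed, n_total = n_total)
  sim <- simulate_trial(cfg)
  cals <- lapply(seq_len(nrow(sim$baseline)), function(i) {
    pid <- sim$baseline$participant_id[i]
    tlfb_calendar(pid, sim$tlfb[sim$tlfb$participant_id == pid, -1],
                  sim$baseline$screening_day[i],
                  sim$baseline$treatment_end_day[i])
  })
  list(cfg = cfg, sim = sim, calendars = cals)
}
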