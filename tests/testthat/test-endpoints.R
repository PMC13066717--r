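test_that("days since last drink counts the terminal abstinent run", {
  # five zero days then a drinking day
  cal <- dense_calendar(fill = 2, overrides = stats::setNames(
    rep(0, 5), as.character(-1:-5)))
  expect_equal(days_since_last_drink(cal), 5L)
  # drink on the eve of randomization
  cal2 <- dense_calendar(fill = 0, overrides = c("-1" = 2))
  expect_equal(days_since_last_drink(cal2), 0L)
  # a missing day terminates the run
  cal3 <- dense_calendar(fill = 2, overrides = c("-1" = 0, "-2" = 0,
                                                 "-3" = 0, "-4" = NA))
  expect_equal(days_since_last_drink(cal3), 3L)
  expect_equal(oracle_dsld(cal3), 3L)
  # fully abstinent observed history: capped at its length, no extrapolation
  cal4 <- dense_calendar(screening_day = -14L, fill = 0)
  expect_equal(days_since_last_drink(cal4), 42L)
})

test_that("days since last drink matches the backward-scan oracle", {
  set.seed(21)
  for (i in 1:300) {
    cal <- random_calendar()
    expect_equal(days_since_last_drink(cal), oracle_dsld(cal))
  }
})

test_that("worst-case imputation drives abstinence and no-heavy endpoints", {
  allzero <- dense_calendar(fill = 0, treatment_end_day = 28L)
  expect_true(total_abstinence(allzero))
  onemiss <- dense_calendar(fill = 0, overrides = c("10" = NA))
  expect_false(total_abstinence(onemiss))
  onedrink <- dense_calendar(fill = 0, overrides = c("10" = 1))
  expect_false(total_abstinence(onedrink))
  gap <- dense_calendar(fill = 0, drop_days = 12L)
  expect_false(total_abstinence(gap))          # an absent day is a missing day

  four <- dense_calendar(fill = 4)
  expect_true(no_heavy_drinking(four, "male"))   # 4 < the 5-drink male cutoff
  expect_false(no_heavy_drinking(four, "female"))# 4 reaches the female cutoff
  expect_false(no_heavy_drinking(onemiss, "male"))
  five <- dense_calendar(fill = 0, overrides = c("3" = 5))
  expect_false(no_heavy_drinking(five, "male"))
  # thresholds are configurable
  expect_true(no_heavy_drinking(five, "male", heavy_male = 6))
})

test_that("endpoint risk level uses the final 28 days and voids on missing", {
  # ~2.14 drinks/day * 14 g = 30 g/day for a male: low risk
  low <- dense_calendar(fill = 30 / 14, treatment_end_day = 112L)
  expect_equal(as.character(endpoint_rdl(low, "male")), "low")
  zero <- dense_calendar(fill = 0, treatment_end_day = 112L)
  expect_equal(as.character(endpoint_rdl(zero, "male")), "abstinent")
  # dropout at week 8 of a 16-week study: window entirely unreported
  dropout <- dense_calendar(fill = 3, treatment_end_day = 112L,
                            overrides = stats::setNames(
                              rep(NA, 57), as.character(56:112)))
  expect_true(is.na(endpoint_rdl(dropout, "male")))
  # observed-only policy classifies on what was reported
  part <- dense_calendar(fill = 30 / 14, treatment_end_day = 112L,
                         overrides = c("100" = NA))
  expect_true(is.na(endpoint_rdl(part, "male")))
  expect_equal(as.character(endpoint_rdl(part, "male", observed_only = TRUE)),
               "low")
})

test_that("two-level reduction follows integer level arithmetic", {
  expect_true(who2plus_reduction("very_high", "medium"))
  expect_false(who2plus_reduction("medium", "low"))
  expect_true(who2plus_reduction("medium", "abstinent"))
  expect_false(who2plus_reduction("high", NA_character_))
  expect_true(who2plus_reduction("high", "abstinent"))
  expect_false(who2plus_reduction("very_high", "high"))
  expect_error(who2plus_reduction("low", "abstinent"), "baseline")
})

test_that("research completion is presence on the final day, not abstinence", {
  heavy_end <- dense_calendar(fill = 0, overrides = c("28" = 6))
  expect_true(research_completer(heavy_end))
  absent_end <- dense_calendar(fill = 0, drop_days = 28L)
  expect_false(research_completer(absent_end))
  miss_end <- dense_calendar(fill = 0, overrides = c("28" = NA))
  expect_false(research_completer(miss_end))
})

test_that("derived records compose the component operations consistently", {
  cal <- dense_calendar(fill = 0, treatment_end_day = 112L)
  rec <- derive_endpoints(cal, "male", "very_high")
  expect_true(rec$abstinent && rec$no_heavy && rec$who2plus && rec$completer)
  expect_equal(as.character(rec$endpoint_rdl), "abstinent")

  dropout <- dense_calendar(fill = 3, treatment_end_day = 112L,
                            overrides = stats::setNames(
                              rep(NA, 57), as.character(56:112)))
  rec2 <- derive_endpoints(dropout, "male", "very_high")
  expect_false(any(rec2$abstinent, rec2$no_heavy, rec2$who2plus, rec2$completer))

  heavy <- dense_calendar(fill = 8, treatment_end_day = 112L)
  rec3 <- derive_endpoints(heavy, "male", "very_high")
  expect_false(rec3$abstinent || rec3$no_heavy || rec3$who2plus)
  expect_true(rec3$completer)
})

test_that("deleting an observed treatment day never rescues an endpoint", {
  set.seed(31)
  for (i in 1:40) {
    cal <- random_calendar()
    before_a <- total_abstinence(cal)
    before_h <- no_heavy_drinking(cal, "male")
    tr_days <- cal$days$day[cal$days$day >= 0 & !cal$days$missing]
    if (!length(tr_days)) next
    drop <- sample(tr_days, 1)
    cal2 <- tlfb_calendar(cal$participant_id,
                          cal$days[cal$days$day != drop, ],
                          cal$screening_day, cal$treatment_end_day)
    expect_true(total_abstinence(cal2) <= before_a)
    expect_true(no_heavy_drinking(cal2, "male") <= before_h)
  }
})

test_that("vectorized table derivation matches the per-calendar operations", {
  sc <- sim_with_calendars(seed = 404, n_total = 60)
  pp <- sc$sim$baseline[, c("participant_id", "sex", "screening_day",
                            "treatment_end_day")]
  tab <- derive_endpoints_table(sc$sim$tlfb, pp)
  for (i in seq_along(sc$calendars)) {
    cal <- sc$calendars[[i]]
    sex <- sc$sim$baseline$sex[i]
    row <- tab[tab$participant_id == cal$participant_id, ]
    bwin <- extract_window(cal, cal$screening_day, 28, "before")
    brdl <- classify_rdl(mean_daily_grams(bwin), any(bwin$drinks > 0), sex)
    rec <- derive_endpoints(cal, sex, brdl)
    expect_equal(row$abstinent, rec$abstinent)
    expect_equal(row$no_heavy, rec$no_heavy)
    expect_equal(row$who2plus, rec$who2plus)
    expect_equal(row$completer, rec$completer)
    expect_equal(row$dsld, rec$dsld)
    expect_equal(as.character(row$baseline_rdl), as.character(rec$baseline_rdl))
    expect_equal(as.character(row$endpoint_rdl), as.character(rec$endpoint_rdl))
  }
})
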