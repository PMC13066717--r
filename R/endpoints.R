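# Per-participant binary drinking outcomes and days since last drink (DSLD),
# with worst-case imputation of unreported treatment days.

#' Days since last drink at randomization
#'
#' Counts consecutive abstinent days immediately before day 0 (randomization
#' / first dosing), scanning backwards from day -1 and stopping at the first
#' drinking day, missing day, or end of the observed history. Interim days
#' between screening and randomization count automatically because they are
#' part of the calendar.
#'
#' @param cal A [tlfb_calendar()].
#' @return Non-negative integer count.
#' @export
days_since_last_drink <- function(cal) {
  stopifnot(inherits(cal, "tlfb_calendar"))
  d <- -1L
  count <- 0L
  repeat {
    idx <- match(d, cal$days$day)
    if (is.na(idx)) break
    if (cal$days$missing[idx]) break
    if (cal$days$drinks[idx] > 0) break
    count <- count + 1L
    d <- d - 1L
  }
  count
}

heavy_threshold <- function(sex, heavy_male = 5, heavy_female = 4) {
  ifelse(sex == "male", heavy_male, heavy_female)
}

# Treatment-period records, gap-filled as missing, days [0, treatment_end].
treatment_days <- function(cal) {
  extract_window(cal, anchor = cal$treatment_end_day,
                 length = cal$treatment_end_day + 1L, direction = "ending_at")
}

#' Total abstinence over the treatment period
#'
#' `TRUE` iff every treatment day (day 0 through the last treatment day) is
#' observed and reports zero drinks. Unreported days are imputed worst-case
#' as a return to drinking, so any gap or dropout fails the endpoint.
#'
#' @param cal A [tlfb_calendar()].
#' @return Logical.
#' @export
total_abstinence <- function(cal) {
  tr <- treatment_days(cal)
  !any(tr$missing) && all(tr$drinks == 0)
}

#' No heavy drinking days over the treatment period
#'
#' `TRUE` iff no treatment day is missing and none reaches the sex-specific
#' heavy-drinking threshold (>= 5 standard drinks for males, >= 4 for
#' females, the NIAAA convention; configurable). Unreported days are imputed
#' worst-case as heavy drinking days.
#'
#' @param cal A [tlfb_calendar()].
#' @param sex `"male"` or `"female"`.
#' @param heavy_male,heavy_female Heavy-day thresholds in standard drinks.
#' @return Logical.
#' @export
no_heavy_drinking <- function(cal, sex, heavy_male = 5, heavy_female = 4) {
  thr <- heavy_threshold(match.arg(sex, c("male", "female")),
                         heavy_male, heavy_female)
  tr <- treatment_days(cal)
  !any(tr$missing) && all(tr$drinks < thr)
}

#' Endpoint WHO risk drinking level
#'
#' Classifies the WHO risk drinking level over the final 28 treatment days
#' (the window ending at the last treatment day, independent of study
#' length). By default any missing day inside the window voids it and `NA`
#' is returned -- the strictest reading of recoding dropouts and missing
#' data to "no change"; `observed_only = TRUE` instead classifies on the
#' observed window days (and still returns `NA` when none are observed).
#'
#' @param cal A [tlfb_calendar()].
#' @param sex `"male"` or `"female"`.
#' @param cfg A [study_config()] or grams-per-drink number.
#' @param observed_only Classify on observed days only (default `FALSE`).
#' @return Ordered RDL factor of length 1, or `NA`.
#' @export
endpoint_rdl <- function(cal, sex, cfg = 14.0, observed_only = FALSE) {
  win <- extract_window(cal, anchor = cal$treatment_end_day, length = 28L,
                        direction = "ending_at")
  if (observed_only) win <- win[!win$missing, ]
  if (nrow(win) == 0L || any(win$missing)) return(rdl_factor(NA_character_))
  mg <- mean_daily_grams(win, cfg)
  classify_rdl(mg, any_drinking_day = any(win$drinks > 0), sex = sex)
}

#' WHO 2+ risk drinking level reduction
#'
#' Success iff the endpoint level sits at least two ordinal levels below the
#' baseline level. An undefined endpoint (dropout / missing final window) is
#' recoded to "no change", i.e. failure. Baseline must be medium, high or
#' very high risk: lower baselines cannot attain a two-level shift and are
#' excluded upstream. A medium-risk baseline succeeds only via full endpoint
#' abstinence -- that falls out of the integer-shift rule, no special case.
#'
#' @param baseline Baseline RDL (factor or label).
#' @param endpoint Endpoint RDL (factor or label), or `NA`.
#' @return Logical vector.
#' @export
who2plus_reduction <- function(baseline, endpoint) {
  b <- rdl_code(baseline)
  e <- rdl_code(endpoint)
  if (any(is.na(b)) || any(b < 2L)) {
    stop("baseline RDL must be medium, high or very_high (low-risk rows are excluded upstream)")
  }
  ifelse(is.na(e), FALSE, (b - e) >= 2L)
}

#' Research completer status
#'
#' `TRUE` iff the participant reported TLFB data for the final treatment
#' day -- a proxy for study completion (completion is independent of what
#' was drunk that day).
#'
#' @param cal A [tlfb_calendar()].
#' @return Logical.
#' @export
research_completer <- function(cal) {
  idx <- match(cal$treatment_end_day, cal$days$day)
  !is.na(idx) && !cal$days$missing[idx]
}

#' Derive all endpoints for one participant
#'
#' Composes [days_since_last_drink()], [total_abstinence()],
#' [no_heavy_drinking()], [endpoint_rdl()], [who2plus_reduction()] and
#' [research_completer()] into one endpoint record.
#'
#' @param cal A [tlfb_calendar()].
#' @param sex `"male"` or `"female"`.
#' @param baseline_rdl Baseline RDL (medium/high/very_high).
#' @param cfg A [study_config()] or grams-per-drink number.
#' @param heavy_male,heavy_female Heavy-day thresholds in standard drinks.
#' @param observed_only Endpoint-window policy, see [endpoint_rdl()].
#' @return One-row tibble: `participant_id`, `abstinent`, `no_heavy`,
#'   `who2plus`, `completer`, `dsld`, `baseline_rdl`, `endpoint_rdl`.
#' @export
derive_endpoints <- function(cal, sex, baseline_rdl, cfg = 14.0,
                             heavy_male = 5, heavy_female = 4,
                             observed_only = FALSE) {
  erdl <- endpoint_rdl(cal, sex, cfg, observed_only = observed_only)
  tibble::tibble(
    participant_id = cal$participant_id,
    abstinent = total_abstinence(cal),
    no_heavy = no_heavy_drinking(cal, sex, heavy_male, heavy_female),
    who2plus = who2plus_reduction(baseline_rdl, erdl),
    completer = research_completer(cal),
    dsld = days_since_last_drink(cal),
    baseline_rdl = rdl_factor(as.character(baseline_rdl)),
    endpoint_rdl = erdl
  )
}

#' Derive endpoints for a whole trial table
#'
#' Vectorized equivalent of [derive_endpoints()] over a long-format TLFB
#' table; identical results, suitable for simulated trials with thousands of
#' participants. Also computes each participant's baseline RDL from the 28
#' days before screening.
#'
#' @param tlfb Long tibble: `participant_id`, `day`, `drinks`, `missing`.
#' @param participants Tibble with `participant_id`, `sex`, `screening_day`,
#'   `treatment_end_day` (one row per participant).
#' @param grams_per_drink Grams of ethanol per standard drink.
#' @param heavy_male,heavy_female Heavy-day thresholds in standard drinks.
#' @param observed_only Endpoint-window policy, see [endpoint_rdl()].
#' @return Tibble with one row per participant: the [derive_endpoints()]
#'   columns plus `baseline_rdl` computed from the pre-screening month.
#' @export
derive_endpoints_table <- function(tlfb, participants, grams_per_drink = 14.0,
                                   heavy_male = 5, heavy_female = 4,
                                   observed_only = FALSE) {
  stopifnot(all(c("participant_id", "day", "drinks", "missing") %in% names(tlfb)),
            all(c("participant_id", "sex", "screening_day", "treatment_end_day")
                %in% names(participants)))
  dt <- data.table::as.data.table(tlfb)
  pp <- data.table::as.data.table(participants)
  dt <- pp[, c("participant_id", "sex", "screening_day", "treatment_end_day")][
    dt, on = "participant_id"]
  dt[, missing := as.logical(missing)]
  dt[, thr := heavy_threshold(sex, heavy_male, heavy_female)]

  # plain precomputed columns so the grouped sums stay fully vectorized
  obs <- !dt$missing
  d0 <- dt$drinks
  d0[!obs] <- 0
  tr <- dt$day >= 0L & dt$day <= dt$treatment_end_day
  win <- dt$day >= (dt$treatment_end_day - 27L) & dt$day <= dt$treatment_end_day
  bwin <- dt$day >= (dt$screening_day - 28L) & dt$day <= (dt$screening_day - 1L)
  dt[, `:=`(
    n_tr = tr,
    n_tr_miss = tr & !obs,
    n_tr_drink = tr & obs & d0 > 0,
    n_tr_heavy = tr & obs & d0 >= thr,
    n_win = win,
    n_win_miss = win & !obs,
    n_win_obs = win & obs,
    win_sum = d0 * win,
    win_drink = win & obs & d0 > 0,
    n_b = bwin,
    n_b_miss = bwin & !obs,
    b_sum = d0 * bwin,
    b_drink = bwin & obs & d0 > 0,
    at_end = dt$day == dt$treatment_end_day & obs
  )]
  sumcols <- c("n_tr", "n_tr_miss", "n_tr_drink", "n_tr_heavy", "n_win",
               "n_win_miss", "n_win_obs", "win_sum", "win_drink", "n_b",
               "n_b_miss", "b_sum", "b_drink", "at_end")
  agg <- dt[, lapply(.SD, sum), by = "participant_id", .SDcols = sumcols]
  first <- dt[, list(sex = sex[1L], end = treatment_end_day[1L]),
              by = "participant_id"]
  agg <- first[agg, on = "participant_id"]

  # DSLD: rank pre-randomization observed zero-drink days backwards from -1;
  # the run ends at the first rank whose day is out of sequence (a drinking,
  # missing, or absent day).
  pd <- dt[day < 0L, c("participant_id", "day", "missing", "drinks")]
  pd <- pd[order(participant_id, -day)]
  pd[, rnk := seq_len(.N), by = "participant_id"]
  pd[, good := day == -rnk & !missing & drinks == 0]
  npre <- pd[, list(n_pre = .N), by = "participant_id"]
  fb <- pd[good == FALSE, list(first_bad = min(rnk)), by = "participant_id"]
  npre <- fb[npre, on = "participant_id"]
  npre[, dsld := data.table::fifelse(is.na(first_bad), n_pre, first_bad - 1L)]
  agg <- npre[, c("participant_id", "dsld")][agg, on = "participant_id"]
  agg[is.na(dsld), dsld := 0L]

  # worst-case imputation: an absent treatment day counts as missing
  treat_complete <- agg$n_tr == agg$end + 1L & agg$n_tr_miss == 0L
  win_complete <- if (observed_only) agg$n_win_obs > 0L else
    (agg$n_win == 28L & agg$n_win_miss == 0L)
  win_n <- if (observed_only) agg$n_win_obs else 28L
  b_complete <- agg$n_b == 28L & agg$n_b_miss == 0L
  out <- tibble::tibble(
    participant_id = agg$participant_id,
    abstinent = treat_complete & agg$n_tr_drink == 0L,
    no_heavy = treat_complete & agg$n_tr_heavy == 0L,
    completer = agg$at_end > 0L,
    dsld = as.integer(agg$dsld),
    ep_mean = ifelse(win_complete, agg$win_sum / win_n * grams_per_drink,
                     NA_real_),
    ep_any = ifelse(win_complete, agg$win_drink > 0L, NA),
    b_mean = ifelse(b_complete, agg$b_sum / 28 * grams_per_drink, NA_real_),
    b_any = ifelse(b_complete, agg$b_drink > 0L, NA),
    sex = agg$sex
  )
  out$endpoint_rdl <- classify_rdl(
    ifelse(is.na(out$ep_mean), 0, out$ep_mean),
    ifelse(is.na(out$ep_any), FALSE, out$ep_any),
    out$sex)
  out$endpoint_rdl[is.na(out$ep_mean)] <- NA
  out$baseline_rdl <- classify_rdl(
    ifelse(is.na(out$b_mean), 0, out$b_mean),
    ifelse(is.na(out$b_any), FALSE, out$b_any),
    out$sex)
  out$baseline_rdl[is.na(out$b_mean)] <- NA
  bcode <- rdl_code(out$baseline_rdl)
  ecode <- rdl_code(out$endpoint_rdl)
  out$who2plus <- !is.na(bcode) & bcode >= 2L & !is.na(ecode) & (bcode - ecode) >= 2L
  out[, c("participant_id", "abstinent", "no_heavy", "who2plus", "completer",
          "dsld", "baseline_rdl", "endpoint_rdl")]
}
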