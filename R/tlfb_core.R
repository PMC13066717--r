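# Calendar data model, assessment-window extraction, and WHO risk drinking
# level (RDL) classification.

#' WHO risk drinking level labels
#'
#' The five ordinal levels, lowest to highest. Level arithmetic (e.g. a
#' "two-level reduction") is integer subtraction of the codes returned by
#' [rdl_code()].
#'
#' @return Character vector of the five level labels in ascending order.
#' @export
rdl_levels <- function() {
  c("abstinent", "low", "medium", "high", "very_high")
}

#' Build an ordered RDL factor
#'
#' @param x Character vector of level labels, or integer codes 0--4.
#' @return Ordered factor over the five risk levels.
#' @export
rdl_factor <- function(x) {
  if (is.numeric(x)) {
    stopifnot(all(is.na(x) | (x >= 0 & x <= 4 & x == floor(x))))
    x <- rdl_levels()[x + 1L]
  }
  bad <- !is.na(x) & !x %in% rdl_levels()
  if (any(bad)) {
    stop("unknown risk level label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = rdl_levels(), ordered = TRUE)
}

#' Integer code of an RDL (abstinent = 0 ... very_high = 4)
#'
#' @param x Ordered RDL factor or character labels.
#' @return Integer vector of codes.
#' @export
rdl_code <- function(x) {
  if (!is.factor(x)) x <- rdl_factor(x)
  as.integer(x) - 1L
}

#' Per-study treatment configuration
#'
#' @param study_name Study label.
#' @param treatment_weeks Length of the treatment period in weeks (the five
#'   bundled presets span 12--26 weeks).
#' @param titration_weeks,taper_weeks Metadata on dose ramp-up/ramp-down
#'   weeks contained within `treatment_weeks`; not used in endpoint
#'   arithmetic.
#' @param grams_per_drink Grams of ethanol per reported standard drink.
#'   Defaults to the US convention of 14 g.
#' @return A `study_config` list.
#' @export
study_config <- function(study_name, treatment_weeks,
                         titration_weeks = 0L, taper_weeks = 0L,
                         grams_per_drink = 14.0) {
  stopifnot(is.character(study_name), length(study_name) == 1L,
            treatment_weeks >= 1, grams_per_drink > 0)
  structure(
    list(study_name = study_name,
         treatment_weeks = as.integer(treatment_weeks),
         titration_weeks = as.integer(titration_weeks),
         taper_weeks = as.integer(taper_weeks),
         grams_per_drink = grams_per_drink,
         treatment_end_day = as.integer(treatment_weeks) * 7L),
    class = "study_config"
  )
}

#' Bundled study presets
#'
#' Treatment-period presets for the five multi-site AUD pharmacotherapy
#' trials the pipeline emulates (read from the packaged YAML so users can
#' copy and adapt the file for their own studies).
#'
#' @param path Optional path to an alternative presets YAML.
#' @return A tibble with one row per study: `study_name`, `treatment_weeks`,
#'   `titration_weeks`, `taper_weeks`, `grams_per_drink`,
#'   `treatment_end_day`.
#' @export
study_presets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "study_presets.yaml", package = "tlfbtrials")
  }
  raw <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(raw$studies, function(s) {
    tibble::tibble(
      study_name = s$study_name,
      treatment_weeks = as.integer(s$treatment_weeks),
      titration_weeks = as.integer(s$titration_weeks %||% 0L),
      taper_weeks = as.integer(s$taper_weeks %||% 0L),
      grams_per_drink = as.numeric(s$grams_per_drink %||% 14.0),
      treatment_end_day = as.integer(s$treatment_weeks) * 7L
    )
  }))
}

#' One participant's TLFB calendar
#'
#' Daily drinking records on a 0-based study-day axis with randomization /
#' first dosing at day 0; screening and pre-screening days are negative.
#'
#' @param participant_id Identifier.
#' @param days Data frame with columns `day` (integer), `drinks`
#'   (non-negative reals; `NA` allowed only where `missing` is `TRUE`) and
#'   `missing` (logical). Days must be unique.
#' @param screening_day Negative integer: the screening visit day.
#' @param treatment_end_day Positive integer: last treatment day.
#' @return A `tlfb_calendar` object.
#' @export
tlfb_calendar <- function(participant_id, days, screening_day, treatment_end_day) {
  days <- tibble::as_tibble(days)
  stopifnot(all(c("day", "drinks", "missing") %in% names(days)))
  days$day <- as.integer(days$day)
  days$missing <- as.logical(days$missing)
  if (anyDuplicated(days$day)) {
    stop("duplicate day indices in calendar for participant ", participant_id)
  }
  if (any(!days$missing & (is.na(days$drinks) | days$drinks < 0))) {
    stop("observed days must have non-negative drinks (participant ",
         participant_id, ")")
  }
  if (!(screening_day < 0 && treatment_end_day > 0)) {
    stop("need screening_day < 0 < treatment_end_day (participant ",
         participant_id, ")")
  }
  days <- days[order(days$day), ]
  structure(
    list(participant_id = participant_id,
         days = days,
         screening_day = as.integer(screening_day),
         treatment_end_day = as.integer(treatment_end_day)),
    class = "tlfb_calendar"
  )
}

#' @export
print.tlfb_calendar <- function(x, ...) {
  cat(sprintf(
    "<tlfb_calendar> participant %s: days %d..%d (%d records, %d missing), screening %d, treatment end %d\n",
    x$participant_id, min(x$days$day), max(x$days$day), nrow(x$days),
    sum(x$days$missing), x$screening_day, x$treatment_end_day))
  invisible(x)
}

# Declared coverage span of a calendar: the stored records extended to the
# nominal baseline month and treatment end, so that window extraction over a
# dropout tail is a gap-fill, not an error.
calendar_span <- function(cal) {
  range(c(cal$days$day, cal$screening_day - 28L, cal$treatment_end_day))
}

#' Extract a fixed-length assessment window from a calendar
#'
#' Returns exactly `length` daily records. `direction = "before"` covers
#' days `[anchor - length, anchor - 1]` (e.g. the baseline month before the
#' screening visit); `direction = "ending_at"` covers
#' `[anchor - length + 1, anchor]` (e.g. the final 28 treatment days). Days
#' absent from the calendar are returned as `missing = TRUE` records.
#'
#' @param cal A [tlfb_calendar()].
#' @param anchor Study-day index anchoring the window.
#' @param length Window length in days (>= 1).
#' @param direction `"before"` or `"ending_at"`.
#' @return Tibble with `length` rows: `day`, `drinks`, `missing`.
#' @export
extract_window <- function(cal, anchor, length = 28L,
                           direction = c("before", "ending_at")) {
  direction <- match.arg(direction)
  stopifnot(inherits(cal, "tlfb_calendar"), length >= 1)
  span <- calendar_span(cal)
  if (anchor < span[1] || anchor > span[2]) {
    stop(sprintf("anchor day %d outside calendar span [%d, %d] for participant %s",
                 anchor, span[1], span[2], cal$participant_id))
  }
  want <- if (direction == "before") {
    seq.int(anchor - length, anchor - 1L)
  } else {
    seq.int(anchor - length + 1L, anchor)
  }
  idx <- match(want, cal$days$day)
  out <- tibble::tibble(
    day = as.integer(want),
    drinks = cal$days$drinks[idx],
    missing = cal$days$missing[idx]
  )
  out$missing[is.na(idx)] <- TRUE
  out$drinks[out$missing] <- NA_real_
  out
}

#' Mean daily grams of ethanol over a window
#'
#' Converts standard drinks to grams and averages over every day in the
#' window. If any window day is missing the mean is undefined and `NA` is
#' returned; the caller (the endpoints layer) owns the imputation policy.
#'
#' @param window Tibble of daily records as from [extract_window()].
#' @param cfg A [study_config()] (supplies `grams_per_drink`), or a single
#'   number interpreted as grams per drink.
#' @return Mean grams/day, or `NA_real_` if any day is missing.
#' @export
mean_daily_grams <- function(window, cfg = 14.0) {
  gpd <- if (inherits(cfg, "study_config")) cfg$grams_per_drink else as.numeric(cfg)
  stopifnot(gpd > 0)
  if (nrow(window) == 0L) stop("empty window")
  if (any(window$missing)) return(NA_real_)
  mean(window$drinks) * gpd
}

# Sex-specific gram/day cutpoints separating low|medium, medium|high and
# high|very_high; intervals are half-open on the left, closed on the right.
rdl_gram_cutpoints <- function(sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (sex == "male") c(40, 60, 100) else c(20, 40, 60)
}

#' Classify a WHO risk drinking level
#'
#' Maps mean daily grams of ethanol over a 28-day window to the ordinal WHO
#' risk drinking level, with sex-specific thresholds: for males low risk is
#' (0, 40] g/day, medium (40, 60], high (60, 100] and very high > 100; for
#' females the bands are (0, 20], (20, 40], (40, 60] and > 60. A participant
#' is abstinent only if the window contains no drinking day at all.
#' Vectorized over all three arguments.
#'
#' @param mean_grams Non-negative mean grams/day.
#' @param any_drinking_day Logical: was there at least one drinking day in
#'   the window?
#' @param sex `"male"` or `"female"`.
#' @return Ordered RDL factor.
#' @export
classify_rdl <- function(mean_grams, any_drinking_day, sex) {
  if (any(!is.na(mean_grams) & mean_grams < 0)) stop("mean_grams must be >= 0")
  if (any(!sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  n <- max(length(mean_grams), length(any_drinking_day), length(sex))
  mean_grams <- rep_len(mean_grams, n)
  any_drinking_day <- rep_len(as.logical(any_drinking_day), n)
  sex <- rep_len(sex, n)
  cut1 <- ifelse(sex == "male", 40, 20)
  cut2 <- ifelse(sex == "male", 60, 40)
  cut3 <- ifelse(sex == "male", 100, 60)
  code <- ifelse(!any_drinking_day, 0L,
          ifelse(mean_grams <= cut1, 1L,
          ifelse(mean_grams <= cut2, 2L,
          ifelse(mean_grams <= cut3, 3L, 4L))))
  code[is.na(mean_grams) & any_drinking_day] <- NA_integer_
  rdl_factor(code)
}

#' WHO risk drinking level threshold table
#'
#' The gram/day bands behind [classify_rdl()], one row per level and sex.
#'
#' @return Tibble with `level`, `sex`, `lower` (exclusive), `upper`
#'   (inclusive; `Inf` for very high risk).
#' @export
rdl_threshold_table <- function() {
  rows <- lapply(c("male", "female"), function(s) {
    cp <- rdl_gram_cutpoints(s)
    tibble::tibble(
      level = rdl_factor(c("low", "medium", "high", "very_high")),
      sex = s,
      lower = c(0, cp),
      upper = c(cp, Inf)
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
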