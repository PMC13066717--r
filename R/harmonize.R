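# Merging per-study baseline tables into the analysis dataset: demographic
# recoding, low-risk exclusion, and multi-study concatenation.

#' Default demographic category dictionaries
#'
#' Mapping dictionaries used by [recode_demographics()]: which raw marital
#' and employment categories collapse to `TRUE`, the ordinal income bands at
#' or above the $60,000/year split, the education-year and cigarettes/day
#' thresholds, and urine-screen labels. The five emulated trials used
#' different instruments, so real analyses supply per-study dictionaries
#' (e.g. from YAML); these defaults match the synthetic generator's
#' vocabulary.
#'
#' @return Named list of dictionaries.
#' @export
default_category_maps <- function() {
  list(
    married_cohab_true = c("married", "cohabitating"),
    married_cohab_false = c("separated", "divorced", "widowed", "never married"),
    employed_true = c("full time", "part time"),
    employed_false = c("unemployed", "disabled", "retired", "student", "military"),
    income_bands_60k_plus = c("60-80k", "80-100k", "100k+"),
    income_bands_below_60k = c("<20k", "20-40k", "40-60k"),
    education_years_threshold = 12,
    cigarettes_threshold = 10,
    thc_positive = c("positive"),
    thc_negative = c("negative"),
    race_white = "white",
    race_black = "black",
    race_other = c("mixed", "native american", "asian/pacific islander")
  )
}

map_binary <- function(x, true_set, false_set, field) {
  x <- tolower(trimws(as.character(x)))
  bad <- !x %in% c(true_set, false_set)
  if (any(bad)) {
    stop(sprintf("unmappable %s value(s): %s", field,
                 paste(unique(x[bad]), collapse = ", ")))
  }
  x %in% true_set
}

#' Recode raw per-study demographics to the harmonized binary scheme
#'
#' Collapses the study-specific instruments to the shared binary covariates:
#' married/cohabitating vs all other marital states; employed full or part
#' time vs other statuses; household income dichotomized at $60,000/year
#' (the split closest to even across the pooled trials); 12+ years of
#' education; smoking 10+ cigarettes/day; THC positivity from the baseline
#' urine screen; and non-exclusive White / Black / Hispanic indicators (the
#' remaining race categories are too sparse for indicators and are retained
#' without one).
#'
#' @param raw Tibble of raw baseline records with columns `participant_id`,
#'   `study`, `arm` (`"placebo"`/`"active"`), `sex`, `age`, `marital`,
#'   `employment`, `income_band`, `education_years`, `cigarettes_per_day`,
#'   `urine_thc`, `race`, `hispanic` (logical or 0/1).
#' @param maps Category dictionaries, see [default_category_maps()].
#' @return Tibble of harmonized `participant_baseline` rows.
#' @export
recode_demographics <- function(raw, maps = default_category_maps()) {
  raw <- tibble::as_tibble(raw)
  need <- c("participant_id", "study", "arm", "sex", "age", "marital",
            "employment", "income_band", "education_years",
            "cigarettes_per_day", "urine_thc", "race", "hispanic")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("raw baseline table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(!raw$arm %in% c("placebo", "active"))) {
    stop("arm must be 'placebo' or 'active'")
  }
  if (any(!is.na(raw$age) & raw$age <= 0)) stop("age must be positive")
  race <- tolower(trimws(as.character(raw$race)))
  known <- c(maps$race_white, maps$race_black, maps$race_other)
  if (any(!race %in% known)) {
    stop("unmappable race value(s): ",
         paste(unique(race[!race %in% known]), collapse = ", "))
  }
  tibble::tibble(
    participant_id = as.character(raw$participant_id),
    study = as.character(raw$study),
    arm = raw$arm,
    sex = raw$sex,
    age = as.numeric(raw$age),
    married_cohab = map_binary(raw$marital, maps$married_cohab_true,
                               maps$married_cohab_false, "marital"),
    employed = map_binary(raw$employment, maps$employed_true,
                          maps$employed_false, "employment"),
    income_60k = map_binary(raw$income_band, maps$income_bands_60k_plus,
                            maps$income_bands_below_60k, "income_band"),
    education_12plus = raw$education_years >= maps$education_years_threshold,
    smoker_10plus = raw$cigarettes_per_day >= maps$cigarettes_threshold,
    thc_positive = map_binary(raw$urine_thc, maps$thc_positive,
                              maps$thc_negative, "urine_thc"),
    race_white = race %in% maps$race_white,
    race_black = race %in% maps$race_black,
    race_hispanic = as.logical(raw$hispanic),
    race_raw = race
  )
}

#' Merge per-study analysis tables
#'
#' Concatenates per-study tables into one, preserving the study label for
#' use as a model covariate. Participant ids duplicated across studies are
#' disambiguated by prefixing with the study name.
#'
#' @param tables List of tibbles with identical columns.
#' @return One concatenated tibble.
#' @export
merge_studies <- function(tables) {
  tables <- tables[vapply(tables, nrow, 1L) > 0]
  if (!length(tables)) return(tibble::tibble())
  cols <- lapply(tables, names)
  ref <- cols[[1]]
  for (i in seq_along(cols)) {
    miss <- setdiff(ref, cols[[i]])
    extra <- setdiff(cols[[i]], ref)
    if (length(miss) || length(extra)) {
      stop(sprintf("schema mismatch in table %d: missing [%s], unexpected [%s]",
                   i, paste(miss, collapse = ", "), paste(extra, collapse = ", ")))
    }
  }
  out <- dplyr::bind_rows(tables)
  if (anyDuplicated(out$participant_id)) {
    out$participant_id <- paste(out$study, out$participant_id, sep = ":")
    if (anyDuplicated(out$participant_id)) {
      stop("participant ids not unique even after study prefixing")
    }
  }
  out
}

#' Apply the baseline low-risk exclusion
#'
#' Removes participants whose baseline WHO risk drinking level is abstinent
#' or low risk: their drinking cannot attain a two-level reduction, so they
#' are excluded from all models. Also logs how many participants fall in
#' race categories retained without an indicator column.
#'
#' @param table Analysis tibble with `baseline_rdl` (and optionally
#'   `race_raw`, `race_white`, `race_black`).
#' @return List: `table` (retained rows) and `log` (counts: input, excluded
#'   low-risk, excluded missing baseline, retained, and per-category counts
#'   of races without indicators).
#' @export
apply_exclusions <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot("baseline_rdl" %in% names(table))
  code <- rdl_code(table$baseline_rdl)
  low <- !is.na(code) & code < 2L
  nobase <- is.na(code)
  keep <- !(low | nobase)
  race_counts <- if (all(c("race_raw", "race_white", "race_black") %in% names(table))) {
    no_ind <- !(table$race_white | table$race_black)
    as.list(table(table$race_raw[keep & no_ind]))
  } else list()
  out <- table[keep, ]
  if (nrow(out) == 0L) warning("all rows excluded: no eligible baseline risk levels")
  list(
    table = out,
    log = list(
      n_input = nrow(table),
      n_excluded_low_risk = sum(low),
      n_excluded_missing_baseline = sum(nobase),
      n_retained = nrow(out),
      races_without_indicator = race_counts
    )
  )
}

#' Build the harmonized analysis table
#'
#' Joins harmonized baselines with derived endpoint records, applies the
#' low-risk exclusion and returns the table with its exclusion log and
#' per-study provenance counts.
#'
#' @param baseline Harmonized baseline tibble ([recode_demographics()]).
#' @param endpoints Endpoint tibble ([derive_endpoints_table()]).
#' @return List: `table`, `log`, `study_counts`.
#' @export
build_analysis_table <- function(baseline, endpoints) {
  tab <- dplyr::inner_join(baseline, endpoints, by = "participant_id")
  if (nrow(tab) < nrow(baseline)) {
    warning(sprintf("%d baseline rows had no TLFB-derived endpoints and were dropped",
                    nrow(baseline) - nrow(tab)))
  }
  ex <- apply_exclusions(tab)
  ex$study_counts <- as.list(table(ex$table$study))
  ex
}
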