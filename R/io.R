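# Readers/writers, configuration validation, and the end-to-end pipeline.
#
# CSV (RFC 4180) everywhere, booleans serialized 0/1; JSON for logs and
# manifests; YAML for structured configuration. The exported functions are
# the command surface: simulate/derive/harmonize/analyze correspond to
# write_trial() + derive_endpoints_table() + build_analysis_table() +
# fit_outcome_model()/roc_youden(), and run_pipeline() chains them.

#' Read a long-format TLFB CSV
#'
#' Expects header `participant_id,day,drinks,missing` with `missing` in
#' {0,1} and `drinks` empty exactly when `missing = 1`. Malformed rows
#' (negative drinks, non-integer days, drinks reported on missing days) are
#' rejected with their line numbers; nothing is silently coerced.
#'
#' @param path CSV path.
#' @return Tibble: `participant_id` (character), `day` (integer), `drinks`
#'   (double, `NA` where missing), `missing` (logical).
#' @export
read_tlfb <- function(path) {
  raw <- utils::read.csv(path, colClasses = c(participant_id = "character"),
                         stringsAsFactors = FALSE)
  need <- c("participant_id", "day", "drinks", "missing")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("TLFB file lacks columns: ", paste(miss, collapse = ", "))
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  if (!is.numeric(raw$day) || any(raw$day != floor(raw$day))) {
    bad <- line[!is.finite(raw$day) | raw$day != floor(raw$day)]
    stop("non-integer day at line(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(!raw$missing %in% c(0L, 1L))) {
    bad <- line[!raw$missing %in% c(0L, 1L)]
    stop("missing flag not 0/1 at line(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  m <- raw$missing == 1L
  if (any(!m & (is.na(raw$drinks) | raw$drinks < 0))) {
    bad <- line[!m & (is.na(raw$drinks) | raw$drinks < 0)]
    stop("observed day with absent or negative drinks at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(m & !is.na(raw$drinks))) {
    bad <- line[m & !is.na(raw$drinks)]
    stop("missing day carries a drinks value at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  tibble::tibble(participant_id = raw$participant_id,
                 day = as.integer(raw$day),
                 drinks = as.numeric(raw$drinks),
                 missing = m)
}

#' Read a raw baseline CSV
#'
#' @param path CSV path in the raw per-study dialect consumed by
#'   [recode_demographics()] (plus `screening_day`, `treatment_end_day`).
#' @return Tibble.
#' @export
read_baseline <- function(path) {
  raw <- tibble::as_tibble(
    utils::read.csv(path, colClasses = c(participant_id = "character"),
                    stringsAsFactors = FALSE))
  if (!"participant_id" %in% names(raw)) stop("baseline file lacks participant_id")
  if ("hispanic" %in% names(raw)) raw$hispanic <- as.logical(raw$hispanic)
  raw
}

write_csv01 <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.logical(df[[nm]])) df[[nm]] <- as.integer(df[[nm]])
    if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write a simulated trial to disk
#'
#' Emits `baseline.csv`, `tlfb.csv` and `truth.json` in the dialects the
#' pipeline reads back.
#'
#' @param sim Result of [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bp <- file.path(dir, "baseline.csv")
  tp <- file.path(dir, "tlfb.csv")
  up <- file.path(dir, "truth.json")
  write_csv01(sim$baseline, bp)
  write_csv01(sim$tlfb, tp)
  truth <- sim$truth
  truth$config$studies <- as.data.frame(truth$config$studies)
  truth$participants <- as.data.frame(truth$participants)
  jsonlite::write_json(truth, up, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(c(baseline = bp, tlfb = tp, truth = up))
}

#' Write endpoint records to CSV
#'
#' `participant_id,abstinent,no_heavy,who2plus,completer,dsld,baseline_rdl,endpoint_rdl`
#' with booleans as 0/1 and risk levels as labels.
#'
#' @param endpoints Endpoint tibble.
#' @param path Output path.
#' @export
write_endpoints <- function(endpoints, path) {
  write_csv01(endpoints, path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of an end-to-end run and validates it before any
#' computation; all defaults are echoed into the run manifest.
#'
#' @param input Either a [simulation_config()] (simulate mode) or a list
#'   `list(baseline = path, tlfb = path)` of CSVs to load.
#' @param grams_per_drink Grams of ethanol per standard drink.
#' @param heavy_male,heavy_female Heavy-drinking-day thresholds (standard
#'   drinks).
#' @param observed_only Endpoint-window policy, see [endpoint_rdl()].
#' @param alpha,m Familywise alpha and number of tests for the Bonferroni
#'   threshold.
#' @param outcomes Outcomes to model.
#' @param subset `"all"` or `"placebo_only"` model subset(s) to fit.
#' @param roc_predictor Predictor for ROC/Youden cutoff discovery.
#' @param category_maps Demographic dictionaries for [recode_demographics()].
#' @param seed Seed controlling any simulation.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = simulation_config(),
                            grams_per_drink = 14.0,
                            heavy_male = 5, heavy_female = 4,
                            observed_only = FALSE,
                            alpha = 0.05, m = 4L,
                            outcomes = outcome_labels(),
                            subset = "all",
                            roc_predictor = "dsld",
                            category_maps = default_category_maps(),
                            seed = 1L) {
  mode <- if (inherits(input, "simulation_config")) "simulate" else "load"
  if (mode == "load") {
    stopifnot(is.list(input), all(c("baseline", "tlfb") %in% names(input)))
    for (p in unlist(input[c("baseline", "tlfb")])) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
  }
  stopifnot(grams_per_drink > 0, heavy_male > 0, heavy_female > 0,
            alpha > 0, alpha < 1, m >= 1,
            all(outcomes %in% outcome_labels()),
            all(subset %in% c("all", "placebo_only")))
  structure(
    list(mode = mode, input = input, grams_per_drink = grams_per_drink,
         heavy_male = heavy_male, heavy_female = heavy_female,
         observed_only = observed_only, alpha = alpha, m = as.integer(m),
         outcomes = outcomes, subset = subset, roc_predictor = roc_predictor,
         category_maps = category_maps, seed = as.integer(seed)),
    class = "pipeline_config")
}

config_echo <- function(cfg) {
  ech <- unclass(cfg)
  ech$category_maps <- NULL
  if (cfg$mode == "simulate") {
    sc <- unclass(ech$input)
    sc$studies <- as.data.frame(sc$studies)
    ech$input <- sc
  }
  ech
}

#' Run the full pipeline
#'
#' Simulate-or-load, derive endpoints, harmonize, analyze. Writes (when
#' `out_dir` is given) the analysis table, endpoint table, coefficient
#' tables, ROC coordinate tables, the cutoff contingency report, the
#' exclusion log and a machine-readable run manifest (input hashes, full
#' configuration echo, package version).
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List: `analysis` (table + logs), `endpoints`, `fits`, `rocs`
#'   (per-outcome [roc_youden()] results), `cutoffs` (contingency table at
#'   each outcome's optimal cutoff), `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  input_hashes <- list()
  if (cfg$mode == "simulate") {
    sim_cfg <- cfg$input
    sim_cfg$seed <- cfg$seed
    sim <- simulate_trial(sim_cfg)
    baseline_raw <- sim$baseline
    tlfb <- sim$tlfb
  } else {
    baseline_raw <- read_baseline(cfg$input$baseline)
    tlfb <- read_tlfb(cfg$input$tlfb)
    input_hashes <- as.list(tools::md5sum(unlist(cfg$input[c("baseline", "tlfb")])))
  }
  if (!all(c("screening_day", "treatment_end_day") %in% names(baseline_raw))) {
    stop("baseline table must carry screening_day and treatment_end_day anchors")
  }
  harmonized <- recode_demographics(baseline_raw, cfg$category_maps)
  harmonized$screening_day <- baseline_raw$screening_day
  harmonized$treatment_end_day <- baseline_raw$treatment_end_day
  eps <- derive_endpoints_table(
    tlfb, harmonized[, c("participant_id", "sex", "screening_day",
                         "treatment_end_day")],
    grams_per_drink = cfg$grams_per_drink,
    heavy_male = cfg$heavy_male, heavy_female = cfg$heavy_female,
    observed_only = cfg$observed_only)
  an <- build_analysis_table(harmonized, eps)
  thr <- bonferroni_threshold(cfg$alpha, cfg$m)
  fits <- list()
  for (sb in cfg$subset) {
    for (oc in cfg$outcomes) {
      fits[[paste(oc, sb, sep = ".")]] <-
        fit_outcome_model(an$table, oc, sb, sig_threshold = thr)
    }
  }
  rocs <- lapply(stats::setNames(cfg$outcomes, cfg$outcomes), function(oc)
    roc_youden(an$table[[cfg$roc_predictor]], an$table[[oc]]))
  cutoffs <- lapply(rocs, function(r)
    cutoff_table(an$table, r$optimal_cutoff, predictor = cfg$roc_predictor,
                 outcomes = cfg$outcomes, sig_threshold = thr))
  manifest <- list(
    package_version = as.character(utils::packageVersion("tlfbtrials")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = cfg$mode,
    input_hashes = input_hashes,
    config = config_echo(cfg),
    n_analysis = nrow(an$table),
    exclusion_log = an$log
  )
  res <- list(analysis = an, endpoints = eps, fits = fits, rocs = rocs,
              cutoffs = cutoffs, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv01(an$table, file.path(out_dir, "analysis.csv"))
    write_endpoints(eps, file.path(out_dir, "endpoints.csv"))
    for (nm in names(fits)) {
      write_csv01(fits[[nm]]$coefficients,
                  file.path(out_dir, paste0("coefficients_", nm, ".csv")))
    }
    for (nm in names(rocs)) {
      write_csv01(rocs[[nm]]$coords,
                  file.path(out_dir, paste0("roc_", nm, ".csv")))
      write_csv01(cutoffs[[nm]],
                  file.path(out_dir, paste0("cutoff_table_", nm, ".csv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}
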