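#' @importFrom data.table := as.data.table fifelse
#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  "missing", "drinks0", "thr", "day", "treatment_end_day", "screening_day",
  "sex", "drinks", "participant_id", "rnk", "good", "first_bad", "n_pre",
  "dsld", ".N", ".SD"
))
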