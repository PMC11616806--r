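# Printed-result fixtures: the deterministic, scenario, PSA and subgroup
# tables of the source analysis, stored verbatim (including their rounding
# artefacts) for reporting-layer tests.  These are published per-arm
# results, not model inputs.

#' Available printed-fixture table identifiers
#'
#' @return Character vector of table ids.
#' @export
printed_table_ids <- function() {
  c("T2_lifetime", "T2_2yr", "T2_5yr", "T3", "T4", "T5",
    "T6_I1", "T6_I23", "T6_I45")
}

#' Load a printed results fixture
#'
#' Returns the verbatim printed values of one results table: per-arm
#' expected life years, QALYs, costs and death percentages where given,
#' the printed incrementals and ICERs, and for the probabilistic table the
#' 95% interval bounds.  Values are stored exactly as printed, including
#' rounding inconsistencies (e.g. a printed incremental cost one pound off
#' the difference of the printed per-arm costs), so tests against them use
#' the printed-incremental convention.
#'
#' @param table_id One of [printed_table_ids()].
#' @return A tibble with columns `table_id`, `metric`, `arm`, `value`,
#'   `lo`, `hi` (interval bounds are `NA` except for the PSA table).
#' @export
#' @examples
#' load_printed_fixture("T2_lifetime")
load_printed_fixture <- function(table_id) {
  if (!is.character(table_id) || length(table_id) != 1L ||
      !table_id %in% printed_table_ids()) {
    abort(sprintf("unknown table id '%s'; see printed_table_ids()",
                  paste(table_id, collapse = ", ")))
  }
  path <- system.file("extdata", "printed_tables.csv", package = "lvadcea",
                      mustWork = TRUE)
  all <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  dplyr::filter(all, .data$table_id == !!table_id)
}
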