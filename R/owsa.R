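# One-way deterministic sensitivity analysis with tornado ordering.

#' One-way deterministic sensitivity analysis
#'
#' Reruns the full deterministic model with each listed parameter at its
#' low and at its high value, all else at base, and collects the lifetime
#' ICER per QALY at both ends.  Entries are sorted descending by the width
#' of the ICER range (the tornado ordering).
#'
#' @param params Base-case parameter set.
#' @param ranges A data frame with columns `parameter` (dotted path), `low`,
#'   `high`; each range must bracket (or equal) the base value.
#' @param horizon Months, `Inf` for lifetime.
#' @param life_table Life table supplying background mortality.
#' @return A `lvad_tornado` tibble with columns `parameter`, `base`, `low`,
#'   `high`, `icer_low`, `icer_high`, `width`, sorted by `width` descending.
#' @export
#' @examples
#' \donttest{
#' tor <- run_owsa(default_parameters(), default_owsa_ranges())
#' tor$parameter[1]
#' }
run_owsa <- function(params, ranges = default_owsa_ranges(params),
                     horizon = Inf, life_table = default_life_table()) {
  needed <- c("parameter", "low", "high")
  if (!all(needed %in% names(ranges))) {
    abort("`ranges` needs columns parameter, low, high")
  }
  H <- resolve_horizon(params, horizon)
  icer_at <- function(path, value) {
    p <- validate_parameters(param_set(params, path, value))
    cea <- incremental_analysis(run_arm(p, "LVAD", H, life_table),
                                run_arm(p, "MM", H, life_table))
    cea$icer_per_qaly
  }
  rows <- purrr::pmap(ranges[needed], function(parameter, low, high) {
    base <- param_get(params, parameter)
    if (low > base + 1e-12 || high < base - 1e-12) {
      abort(sprintf("range for '%s' does not bracket the base value %.6g",
                    parameter, base))
    }
    icer_low <- icer_at(parameter, low)
    icer_high <- icer_at(parameter, high)
    tibble::tibble(parameter = parameter, base = base, low = low, high = high,
                   icer_low = icer_low, icer_high = icer_high,
                   width = abs(icer_high - icer_low))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$width))
  class(out) <- c("lvad_tornado", class(out))
  out
}

#' Default one-way sensitivity ranges
#'
#' A set of ranges over the parameters that drive the comparison: ongoing
#' outpatient costs for both arms (wide, reflecting the spread of
#' literature estimates), arm-level mortality multipliers, baseline
#' utilities, the device price and the most frequent complication.
#'
#' @param params Base-case parameter set (ranges are centred on its values).
#' @return A tibble with columns `parameter`, `low`, `high`.
#' @export
default_owsa_ranges <- function(params = default_parameters()) {
  g <- function(path) param_get(params, path)
  u_lv <- g("utilities.lvad_baseline")
  tibble::tribble(
    ~parameter, ~low, ~high,
    "costs.outpatient_lvad_monthly", min(150, g("costs.outpatient_lvad_monthly")),
      g("costs.outpatient_lvad_monthly") + 1400,
    "costs.outpatient_mm_monthly", 0.7 * g("costs.outpatient_mm_monthly"),
      1.3 * g("costs.outpatient_mm_monthly"),
    "mortality.lvad_multiplier", 0.8, 1.25,
    "mortality.mm_multiplier", 0.8, 1.25,
    "utilities.lvad_baseline", u_lv - 0.05, min(1, u_lv + 0.05),
    "utilities.mm_baseline", g("utilities.mm_baseline") - 0.05,
      g("utilities.mm_baseline") + 0.05,
    "costs.device", 0.9 * g("costs.device"), 1.1 * g("costs.device"),
    "complications.gib.prob", 0.5 * g("complications.gib.prob"),
      1.5 * g("complications.gib.prob")
  )
}

#' Export a tornado table to delimited text
#'
#' @param tornado A `lvad_tornado` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(tornado, path) {
  write.csv(tornado, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
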