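# broom-style tidiers for the result objects.

#' Tidy a cost-effectiveness run into the deterministic table shape
#'
#' One row per horizon and metric, with per-arm values and the incremental
#' (the published deterministic-outcomes layout).
#'
#' @param x A `lvad_cea_run` from [run_cea()].
#' @param ... Unused.
#' @return A tibble with columns `horizon`, `metric`, `mm`, `lvad`,
#'   `incremental`.
#' @method tidy lvad_cea_run
#' @export
tidy.lvad_cea_run <- function(x, ...) {
  purrr::map_dfr(names(x$horizons), function(nm) {
    h <- x$horizons[[nm]]
    deaths <- function(r) {
      d <- r$cumulative_deaths[paste0("cycle_", r$horizon)]
      if (length(d)) unname(d) else NA_real_
    }
    tibble::tibble(
      horizon = nm,
      metric = c("deaths", "ly", "qaly", "cost", "icer_per_ly", "icer_per_qaly"),
      mm = c(deaths(h$mm), h$mm$ly, h$mm$qaly, h$mm$cost, NA, NA),
      lvad = c(deaths(h$lvad), h$lvad$ly, h$lvad$qaly, h$lvad$cost, NA, NA),
      incremental = c(deaths(h$lvad) - deaths(h$mm), h$cea$inc_ly, h$cea$inc_qaly,
                      h$cea$inc_cost, h$cea$icer_per_ly, h$cea$icer_per_qaly))
  })
}

#' One-row summary of a cost-effectiveness run
#'
#' Lifetime incremental outcomes and ICERs, plus the severity weighting when
#' a shortfall analysis was requested.
#'
#' @param x A `lvad_cea_run` from [run_cea()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance lvad_cea_run
#' @export
glance.lvad_cea_run <- function(x, ...) {
  nm <- if ("lifetime" %in% names(x$horizons)) "lifetime" else names(x$horizons)[length(x$horizons)]
  h <- x$horizons[[nm]]
  out <- tibble::tibble(horizon = nm, inc_ly = h$cea$inc_ly,
                        inc_qaly = h$cea$inc_qaly, inc_cost = h$cea$inc_cost,
                        icer_per_ly = h$cea$icer_per_ly,
                        icer_per_qaly = h$cea$icer_per_qaly,
                        dominance = h$cea$dominance)
  if (!is.null(x$shortfall)) {
    out <- dplyr::bind_cols(out, x$shortfall[, c("absolute", "proportional",
                                                 "weight", "weighted_icer")])
  }
  out
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x A `lvad_psa` from [run_psa()].
#' @param ... Unused.
#' @return The summary tibble (metric, mean, 2.5% and 97.5% percentiles).
#' @method tidy lvad_psa
#' @export
tidy.lvad_psa <- function(x, ...) x$summary

#' One-row summary of a probabilistic sensitivity analysis
#'
#' @param x A `lvad_psa` from [run_psa()].
#' @param ... Unused.
#' @return A one-row tibble with draw count, seed and both ICER summaries.
#' @method glance lvad_psa
#' @export
glance.lvad_psa <- function(x, ...) {
  tibble::tibble(n = x$n, seed = x$seed, horizon = x$horizon,
                 mean_inc_qaly = mean(x$draws$inc_qaly),
                 mean_inc_cost = mean(x$draws$inc_cost),
                 icer_ratio_of_means = x$icer_ratio_of_means,
                 icer_mean_of_ratios = x$icer_mean_of_ratios)
}
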