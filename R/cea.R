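# Incremental cost-effectiveness layer: incremental outcomes and ICERs,
# QALY shortfall against the general population, and the severity-modifier
# weighting applied to the ICER.

#' Incremental cost-effectiveness analysis of two arm results
#'
#' Differences are intervention minus comparator; ICERs are the cost
#' difference over the effect difference.  When the signs of incremental
#' cost and effect differ the corresponding dominance flag is set and the
#' ICER is undefined (`NA`); an ICER is likewise undefined when the effect
#' difference is zero or negative.
#'
#' @param intervention,comparator `lvad_arm_result` objects (or lists with
#'   fields `ly`, `qaly`, `cost`, `horizon`, `annual_discount`) computed
#'   under identical horizon and discount settings.
#' @return A `lvad_cea` one-row tibble with `inc_ly`, `inc_qaly`,
#'   `inc_cost`, `icer_per_ly`, `icer_per_qaly`, `dominance`.
#' @export
#' @examples
#' lvad <- list(ly = 4.65, qaly = 3.32, cost = 171621, horizon = 540,
#'              annual_discount = 0.035)
#' mm <- list(ly = 0.92, qaly = 0.46, cost = 18886, horizon = 540,
#'            annual_discount = 0.035)
#' incremental_analysis(lvad, mm)
incremental_analysis <- function(intervention, comparator) {
  for (f in c("ly", "qaly", "cost")) {
    if (!is_scalar_number(intervention[[f]]) || !is_scalar_number(comparator[[f]])) {
      abort(sprintf("both arm results need a numeric `%s`", f))
    }
  }
  if (!is.null(intervention$horizon) && !is.null(comparator$horizon) &&
      !isTRUE(all.equal(intervention$horizon, comparator$horizon))) {
    abort("arm results were computed over different horizons")
  }
  if (!is.null(intervention$annual_discount) && !is.null(comparator$annual_discount) &&
      !isTRUE(all.equal(intervention$annual_discount, comparator$annual_discount))) {
    abort("arm results were computed with different discount rates")
  }
  inc_ly <- intervention$ly - comparator$ly
  inc_qaly <- intervention$qaly - comparator$qaly
  inc_cost <- intervention$cost - comparator$cost
  dominance <- if (inc_cost < 0 && inc_qaly > 0) {
    "intervention_dominates"
  } else if (inc_cost > 0 && inc_qaly < 0) {
    "comparator_dominates"
  } else {
    "none"
  }
  icer <- function(effect) {
    if (dominance != "none" || effect <= 0) NA_real_ else inc_cost / effect
  }
  out <- tibble::tibble(inc_ly = inc_ly, inc_qaly = inc_qaly, inc_cost = inc_cost,
                        icer_per_ly = icer(inc_ly), icer_per_qaly = icer(inc_qaly),
                        dominance = dominance)
  class(out) <- c("lvad_cea", class(out))
  out
}

#' Absolute and proportional QALY shortfall
#'
#' The absolute shortfall is the difference between the expected remaining
#' QALYs of the age- and sex-matched general population and the patient
#' population under the comparator (standard-care) strategy; the
#' proportional shortfall divides that by the general-population remaining
#' QALYs.  The general-population value is a user input (in the source
#' analysis it came from an external shortfall calculator).
#'
#' @param comparator_qalys Expected discounted QALYs under standard care.
#' @param genpop_qalys Expected remaining QALYs in the matched general
#'   population; must be positive.
#' @return A one-row tibble with `absolute` and `proportional`.
#' @export
#' @examples
#' qaly_shortfall(0.46, 10.84)
qaly_shortfall <- function(comparator_qalys, genpop_qalys) {
  if (!is_scalar_number(genpop_qalys) || genpop_qalys <= 0) {
    abort("`genpop_qalys` must be positive")
  }
  if (!is_scalar_number(comparator_qalys) || comparator_qalys < 0) {
    abort("`comparator_qalys` must be non-negative")
  }
  absolute <- genpop_qalys - comparator_qalys
  tibble::tibble(absolute = absolute, proportional = absolute / genpop_qalys)
}

#' Default severity-modifier cutoffs
#'
#' The published severity-modifier bounds used in current UK appraisal
#' practice: weight 1.7 when the absolute QALY shortfall is at least 18 or
#' the proportional shortfall at least 0.95; weight 1.2 at 12 / 0.85; else
#' 1.0.  Boundaries are inclusive.  Supply a modified table to explore
#' alternatives (e.g. a single 0.70 proportional cutoff).
#'
#' @return A tibble with columns `weight`, `absolute_min`, `proportional_min`.
#' @export
nice_severity_cutoffs <- function() {
  tibble::tibble(weight = c(1.7, 1.2, 1.0),
                 absolute_min = c(18, 12, 0),
                 proportional_min = c(0.95, 0.85, 0))
}

#' Severity-modifier weight for a QALY shortfall
#'
#' Returns the highest weight whose absolute **or** proportional cutoff is
#' met (inclusive boundaries).
#'
#' @param absolute Absolute QALY shortfall.
#' @param proportional Proportional QALY shortfall in \[0, 1\].
#' @param cutoffs Cutoff table as from [nice_severity_cutoffs()].
#' @return A single weight (1.0, 1.2 or 1.7 under the default table).
#' @export
#' @examples
#' severity_weight(10.38, 0.96)
severity_weight <- function(absolute, proportional, cutoffs = nice_severity_cutoffs()) {
  if (!all(c("weight", "absolute_min", "proportional_min") %in% names(cutoffs)) ||
      !nrow(cutoffs)) {
    abort("`cutoffs` must have columns weight, absolute_min, proportional_min")
  }
  if (!is_scalar_number(absolute) || !is_scalar_number(proportional)) {
    abort("`absolute` and `proportional` must be numeric scalars")
  }
  cutoffs <- dplyr::arrange(cutoffs, dplyr::desc(.data$weight))
  hit <- absolute >= cutoffs$absolute_min | proportional >= cutoffs$proportional_min
  if (!any(hit)) return(min(cutoffs$weight))
  cutoffs$weight[which(hit)[1L]]
}

#' Severity-weighted ICER
#'
#' Divides the ICER by the severity-modifier weight, equivalent to
#' multiplying the QALY gains by the weight before forming the ratio.
#'
#' @param icer ICER in GBP per QALY.
#' @param weight Severity weight, at least 1.
#' @param round Round to the nearest pound (the reporting convention)?
#' @return Weighted ICER in GBP per QALY.
#' @export
#' @examples
#' weighted_icer(53496, 1.7)
weighted_icer <- function(icer, weight, round = TRUE) {
  if (!is_scalar_number(weight) || weight <= 0) abort("`weight` must be positive")
  if (weight < 1) abort("`weight` below 1 is not a severity modifier")
  out <- icer / weight
  if (round) round(out) else out
}

#' Run the full cost-effectiveness comparison
#'
#' Runs both arms over each requested horizon and assembles per-arm totals,
#' incremental outcomes and ICERs; over the lifetime horizon (when
#' requested and `genpop_qalys` is supplied) also the QALY shortfall,
#' severity weight and weighted ICER.
#'
#' @param params A parameter set.
#' @param horizons Numeric months; use `Inf` for the lifetime horizon.
#' @param genpop_qalys Expected remaining QALYs of the matched general
#'   population (user input for the shortfall analysis), or `NULL` to skip.
#' @param cutoffs Severity cutoff table, see [nice_severity_cutoffs()].
#' @param life_table Life table supplying background mortality.
#' @return A `lvad_cea_run` object; see [tidy.lvad_cea_run()] and
#'   [glance.lvad_cea_run()].
#' @export
#' @examples
#' \donttest{
#' cea <- run_cea(default_parameters(), horizons = c(24, Inf),
#'                genpop_qalys = 10.84)
#' glance(cea)
#' }
run_cea <- function(params, horizons = c(24, 60, Inf), genpop_qalys = NULL,
                    cutoffs = nice_severity_cutoffs(),
                    life_table = default_life_table()) {
  H_life <- lifetime_horizon(params)
  cycles <- vapply(horizons, function(h) resolve_horizon(params, h), integer(1))
  traces <- list(LVAD = run_cohort(params, "LVAD", max(cycles), life_table),
                 MM = run_cohort(params, "MM", max(cycles), life_table))
  payoffs <- list(LVAD = cycle_payoffs(params, "LVAD"),
                  MM = cycle_payoffs(params, "MM"))
  per_horizon <- purrr::map(cycles, function(h) {
    lvad <- accumulate_outcomes(traces$LVAD, payoffs$LVAD, horizon = h)
    mm <- accumulate_outcomes(traces$MM, payoffs$MM, horizon = h)
    list(horizon = h, lvad = lvad, mm = mm,
         cea = incremental_analysis(lvad, mm))
  })
  names(per_horizon) <- ifelse(cycles == H_life, "lifetime", paste0(cycles, "m"))

  shortfall <- NULL
  life_idx <- which(cycles == H_life)
  if (!is.null(genpop_qalys) && length(life_idx)) {
    life <- per_horizon[[life_idx[1L]]]
    sf <- qaly_shortfall(life$mm$qaly, genpop_qalys)
    w <- severity_weight(sf$absolute, sf$proportional, cutoffs)
    shortfall <- tibble::tibble(
      comparator_qalys = life$mm$qaly, genpop_qalys = genpop_qalys,
      absolute = sf$absolute, proportional = sf$proportional, weight = w,
      icer_per_qaly = life$cea$icer_per_qaly,
      weighted_icer = if (is.na(life$cea$icer_per_qaly)) NA_real_ else
        weighted_icer(life$cea$icer_per_qaly, w))
  }
  structure(list(horizons = per_horizon, shortfall = shortfall,
                 params = params), class = "lvad_cea_run")
}

#' @export
print.lvad_cea_run <- function(x, ...) {
  cat("<lvad_cea_run>\n")
  print(tidy(x), n = Inf)
  if (!is.null(x$shortfall)) {
    cat(sprintf("severity weight %.1f -> weighted ICER £%s/QALY\n",
                x$shortfall$weight,
                format(round(x$shortfall$weighted_icer), big.mark = ",")))
  }
  invisible(x)
}
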