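# Cohort engine: forward propagation of state occupancy in monthly cycles,
# and accumulation of discounted life years, QALYs and costs.

#' Run the cohort state-transition model for one arm
#'
#' Propagates the full cohort (mass 1) through monthly cycles:
#' `occupancy[t + 1] = occupancy[t] %*% P(t)`, with death resolved before
#' event transitions each cycle.  The trace records, per cycle, the fraction
#' of the cohort in each state; inflows (new entrants per state per cycle)
#' are kept alongside for one-off cost charging.
#'
#' @param params A parameter set.
#' @param arm `"LVAD"` or `"MM"`.
#' @param horizon Months to simulate, `Inf` or `"lifetime"` for the
#'   lifetime horizon (cycles until the age cap).
#' @param life_table Life table supplying background mortality.
#' @return A `lvad_trace`: an occupancy matrix with `horizon + 1` rows
#'   (cycle 0 first) and one column per state, with the inflow matrix, arm
#'   and settings as attributes.  Use [tibble::as_tibble()] for a tidy
#'   per-cycle view.
#' @export
#' @examples
#' tr <- run_cohort(default_parameters(), "MM", horizon = 24)
#' tail(tibble::as_tibble(tr), 2)
run_cohort <- function(params, arm = c("LVAD", "MM"), horizon = "lifetime",
                       life_table = default_life_table()) {
  arm <- match.arg(arm)
  H <- resolve_horizon(params, horizon)
  btt <- arm == "LVAD" && btt_enabled(params)
  states <- arm_states(arm, btt)
  alive <- setdiff(states, "dead")
  E <- event_flow_matrix(params, arm)
  stay <- diag(E)
  QD <- death_prob_matrix(params, arm, 0:(H - 1L), life_table)

  occ <- matrix(0, H + 1L, length(states), dimnames = list(0:H, states))
  inflow <- matrix(0, H, length(alive), dimnames = list(1:H, alive))
  occ[1L, starting_state(arm)] <- 1

  a <- occ[1L, alive]
  dead <- 0
  for (t in seq_len(H)) {
    qd <- QD[t, ]
    surv <- a * (1 - qd)
    dead <- dead + sum(a * qd)
    a <- drop(surv %*% E)
    inflow[t, ] <- a - surv * stay
    occ[t + 1L, alive] <- a
    occ[t + 1L, "dead"] <- dead
  }

  sums <- rowSums(occ)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("cohort mass not conserved; transition structure is inconsistent")
  }
  structure(occ, class = c("lvad_trace", class(occ)),
            inflow = inflow, arm = arm, states = states,
            start_age = params$population$start_age,
            annual_discount = params$discounting$annual_discount)
}

#' @method as_tibble lvad_trace
#' @export
as_tibble.lvad_trace <- function(x, ...) {
  tb <- tibble::as_tibble(unclass(x)[, , drop = FALSE])
  dplyr::mutate(tb, cycle = 0:(nrow(tb) - 1L), cumulative_deaths = tb$dead,
                .before = 1L)
}

#' Export a cohort trace to delimited text
#'
#' One row per cycle, one column per state, plus a cumulative-death column.
#'
#' @param trace A `lvad_trace` from [run_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  write.csv(as_tibble.lvad_trace(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-cycle payoffs for one arm
#'
#' Assembles, from a parameter set, the quantities attached to states each
#' cycle: annual utility weights after permanent major-event decrements
#' (floored at 0), monthly state costs (arm outpatient cost plus any
#' event-state excess), one-off costs charged on entry to a state (the
#' implant bundle — device, operation, ICU and ward days — on entry to
#' `dt`; episode costs on entry to event states), and the expected
#' per-cycle complication load (cost, and utility decrement applied only in
#' the cycle of occurrence).  Complications attach to device states in the
#' LVAD arm (not post-transplant `ht`); in the MM arm the readmission
#' complication carries cost only.
#'
#' @param params A parameter set.
#' @param arm `"LVAD"` or `"MM"`.
#' @return A list with per-state vectors `state_utility`,
#'   `state_cost_monthly`, `oneoff_cost`, `comp_cost_monthly`,
#'   `comp_decrement`.
#' @export
cycle_payoffs <- function(params, arm = c("LVAD", "MM")) {
  arm <- match.arg(arm)
  btt <- arm == "LVAD" && btt_enabled(params)
  alive <- setdiff(arm_states(arm, btt), "dead")
  util <- params$utilities
  dec <- util$decrements
  costs <- params$costs

  base_u <- if (arm == "LVAD") util$lvad_baseline else util$mm_baseline
  state_utility <- vapply(alive, function(s) {
    switch(s, ht = util$ht %||% base_u,
           max(0, base_u - (dec[[s]] %||% 0)))
  }, numeric(1))

  outpatient <- if (arm == "LVAD") costs$outpatient_lvad_monthly else costs$outpatient_mm_monthly
  state_cost <- vapply(alive, function(s) {
    base <- if (identical(s, "ht")) costs$ht_monthly %||% 0 else outpatient
    base + (costs$state_monthly[[s]] %||% 0)
  }, numeric(1))

  implant <- costs$device + costs$implant_op +
    costs$icu_day * (costs$icu_days %||% 0) +
    costs$ward_day * (costs$ward_days %||% 0)
  oneoff <- vapply(alive, function(s) {
    switch(s, dt = implant, mm = 0, btt = 0,
           ht = costs$event_oneoff$ht %||% 0,
           costs$event_oneoff[[s]] %||% 0)
  }, numeric(1))

  comp_names <- if (arm == "LVAD") {
    setdiff(names(params$complications), "mm_readmission")
  } else {
    intersect("mm_readmission", names(params$complications))
  }
  comp_cost <- 0
  comp_dec <- 0
  for (nm in comp_names) {
    comp <- params$complications[[nm]]
    comp_cost <- comp_cost + comp$prob * comp$cost
    comp_dec <- comp_dec + comp$prob * (comp$decrement %||% 0)
  }
  device_states <- if (arm == "LVAD") setdiff(alive, "ht") else alive
  comp_cost_monthly <- setNames(ifelse(alive %in% device_states, comp_cost, 0), alive)
  comp_decrement <- setNames(ifelse(alive %in% device_states, comp_dec, 0), alive)

  list(state_utility = state_utility, state_cost_monthly = state_cost,
       oneoff_cost = oneoff, comp_cost_monthly = comp_cost_monthly,
       comp_decrement = comp_decrement)
}

#' Accumulate discounted outcomes over a cohort trace
#'
#' Applies, at each cycle `t >= 1`, the discount factor
#' `(1 + rate)^(-t / 12)` to that cycle's life years (1/12 per alive
#' person-cycle), QALYs (state utility divided by 12, net of the expected
#' one-cycle complication decrement, floored at 0) and costs (monthly state
#' costs, expected complication costs, and one-off costs on the cycle's
#' state inflows).  One-off costs attached to the starting state (the LVAD
#' implant bundle) are charged undiscounted at cycle 0.  No half-cycle
#' correction is applied: with monthly cycles the correction is
#' second-order relative to the parameter uncertainty.
#'
#' @param trace A `lvad_trace` from [run_cohort()].
#' @param payoffs Per-state payoffs from [cycle_payoffs()].
#' @param annual_discount Annual discount rate (default: the rate recorded
#'   on the trace, normally 0.035).
#' @param horizon Accumulate over the first `horizon` cycles only
#'   (default: the full trace).
#' @return A `lvad_arm_result`: list with `ly`, `qaly`, `cost` (discounted),
#'   `cumulative_deaths` (named fractions at cycles 24, 60 and horizon end,
#'   where available), `horizon`, `arm`, `annual_discount`.
#' @export
accumulate_outcomes <- function(trace, payoffs,
                                annual_discount = attr(trace, "annual_discount"),
                                horizon = NULL) {
  if (!inherits(trace, "lvad_trace")) abort("`trace` must come from run_cohort()")
  if (!is_scalar_number(annual_discount) || annual_discount < 0) {
    abort("`annual_discount` must be a non-negative rate")
  }
  H_trace <- nrow(trace) - 1L
  H <- if (is.null(horizon)) H_trace else as.integer(horizon)
  if (H < 1 || H > H_trace) abort("`horizon` must lie within the trace")
  alive <- setdiff(attr(trace, "states"), "dead")
  occ <- unclass(trace)[1L + seq_len(H), alive, drop = FALSE]
  inflow <- attr(trace, "inflow")[seq_len(H), , drop = FALSE]
  df <- (1 + annual_discount)^(-(seq_len(H)) / 12)

  u_eff <- pmax(payoffs$state_utility[alive] - payoffs$comp_decrement[alive], 0)
  if (any(payoffs$state_utility < 0)) abort("negative state utility")
  ly <- sum(df * rowSums(occ)) / 12
  qaly <- sum(df * (occ %*% u_eff)) / 12
  cost_cycle <- occ %*% (payoffs$state_cost_monthly[alive] +
                           payoffs$comp_cost_monthly[alive]) +
    inflow %*% payoffs$oneoff_cost[alive]
  cost0 <- sum(unclass(trace)[1L, alive] * payoffs$oneoff_cost[alive])
  cost <- cost0 + sum(df * cost_cycle)

  dead_col <- unclass(trace)[, "dead"]
  marks <- c(24L, 60L, H)
  marks <- marks[marks <= H]
  cum_deaths <- setNames(dead_col[1L + marks], paste0("cycle_", marks))

  structure(list(ly = ly, qaly = qaly, cost = cost,
                 cumulative_deaths = cum_deaths, horizon = H,
                 arm = attr(trace, "arm"), annual_discount = annual_discount),
            class = "lvad_arm_result")
}

#' @export
print.lvad_arm_result <- function(x, ...) {
  cat(sprintf("<%s arm, %d cycles, %.1f%%/yr discount>\n", x$arm, x$horizon,
              100 * x$annual_discount))
  cat(sprintf("  LYs %.3f  QALYs %.3f  cost £%s\n", x$ly, x$qaly,
              format(round(x$cost), big.mark = ",")))
  if (length(x$cumulative_deaths)) {
    cat("  cumulative deaths:",
        paste(sprintf("%s %.1f%%", names(x$cumulative_deaths),
                      100 * x$cumulative_deaths), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method as_tibble lvad_arm_result
#' @export
as_tibble.lvad_arm_result <- function(x, ...) {
  tibble::tibble(arm = x$arm, horizon = x$horizon, ly = x$ly, qaly = x$qaly,
                 cost = x$cost,
                 deaths_end = unname(x$cumulative_deaths[paste0("cycle_", x$horizon)]))
}

#' Run one arm end to end
#'
#' Convenience wrapper: [run_cohort()] then [accumulate_outcomes()] with the
#' arm's payoffs.
#'
#' @inheritParams run_cohort
#' @return A `lvad_arm_result`.
#' @export
#' @examples
#' run_arm(default_parameters(), "MM", horizon = 24)
run_arm <- function(params, arm = c("LVAD", "MM"), horizon = "lifetime",
                    life_table = default_life_table()) {
  arm <- match.arg(arm)
  trace <- run_cohort(params, arm, horizon, life_table)
  accumulate_outcomes(trace, cycle_payoffs(params, arm))
}
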