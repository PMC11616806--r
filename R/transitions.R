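# State space and per-cycle transition structure of the cohort model.
#
# Competing-risk convention (the published sources give only marginal
# probabilities): death is resolved first each cycle; event transitions
# apply to survivors at their stated monthly probabilities; the residual
# mass remains in state.  Because event probabilities are constant over
# cycles while death probabilities are age- and month-dependent, the cycle-t
# matrix factorises as P_t = diag(1 - q_t) E + q_t e_dead, with E the
# constant survivor flow matrix — the engine exploits this.

#' Health states occupied by one arm
#'
#' The LVAD arm occupies `dt` (alive on device, no major event), the
#' major-event states `nds` (non-disabling stroke), `ds` (disabling
#' stroke), `rhf` (right heart failure), `ar` (aortic regurgitation), plus
#' `btt`/`ht` when the bridge-to-transplant scenario is active, and `dead`.
#' The MM arm occupies `mm`, the two stroke states and `dead`.
#'
#' @param arm `"LVAD"` or `"MM"`.
#' @param btt_enabled Include the BTT and HT states?
#' @return Character vector of state names, `dead` last.
#' @export
arm_states <- function(arm = c("LVAD", "MM"), btt_enabled = FALSE) {
  arm <- match.arg(arm)
  if (arm == "LVAD") {
    c("dt", "nds", "ds", "rhf", "ar", if (btt_enabled) c("btt", "ht"), "dead")
  } else {
    c("mm", "nds", "ds", "dead")
  }
}

btt_enabled <- function(params) (params$events$btt %||% 0) > 0

starting_state <- function(arm) if (arm == "LVAD") "dt" else "mm"

# Permitted survivor transitions per arm, with the event probability that
# feeds each cell.  Severity order ds > rhf > ar > nds: a patient's state is
# the worst event experienced, so e.g. rhf may progress to ds but not revert.
survivor_transitions <- function(arm, btt = FALSE) {
  if (arm == "LVAD") {
    out <- list(
      dt  = c(nds = "nds", ds = "ds", rhf = "rhf", ar = "ar"),
      nds = c(ds = "ds", rhf = "rhf", ar = "ar"),
      ds  = c(),
      rhf = c(ds = "ds"),
      ar  = c(ds = "ds", rhf = "rhf")
    )
    if (btt) {
      out$dt <- c(out$dt, btt = "btt")
      out$btt <- c(ht = "ht")
      out$ht <- c()
    }
    out
  } else {
    list(
      mm  = c(nds = "mm_nds", ds = "mm_ds"),
      nds = c(ds = "mm_ds"),
      ds  = c()
    )
  }
}

# Constant survivor flow matrix E over alive states; rows sum to 1.
event_flow_matrix <- function(params, arm) {
  btt <- arm == "LVAD" && btt_enabled(params)
  states <- setdiff(arm_states(arm, btt), "dead")
  trans <- survivor_transitions(arm, btt)
  E <- matrix(0, length(states), length(states), dimnames = list(states, states))
  for (from in states) {
    dests <- trans[[from]]
    total <- 0
    for (to in names(dests)) {
      p <- params$events[[dests[[to]]]] %||% 0
      E[from, to] <- p
      total <- total + p
    }
    if (total > 1 + 1e-12) {
      abort(sprintf(
        "transition row '%s': event probabilities sum to %.4f > 1", from, total))
    }
    E[from, from] <- E[from, from] + (1 - total)
  }
  E
}

# Monthly death probability per alive state for transitions out of cycles
# `cycles` (0-based): blend of sex-averaged background mortality at the
# cohort's current age with the arm's disease mortality (month-24 risk
# frozen thereafter) scaled by the state's event mortality multiplier.
# Returns a length(cycles) x n_alive_states matrix.
death_prob_matrix <- function(params, arm, cycles, life_table) {
  btt <- arm == "LVAD" && btt_enabled(params)
  states <- setdiff(arm_states(arm, btt), "dead")
  pop <- params$population
  ages <- pop$start_age + cycles / 12
  bg <- background_monthly(life_table, ages, pop$female_fraction)
  sched <- if (arm == "LVAD") {
    params$mortality$lvad_monthly * params$mortality$lvad_multiplier
  } else {
    params$mortality$mm_monthly * params$mortality$mm_multiplier
  }
  month <- pmin(cycles + 1L, 24L)
  disease <- pmin(sched[month], 1)
  mults <- params$mortality$event_multipliers
  base_state <- if (arm == "LVAD") "dt" else "mm"
  qd <- vapply(states, function(s) {
    m <- mults[[s]] %||% mults[[base_state]] %||% 1
    blend_mortality(bg, pmin(disease * m, 1))
  }, numeric(length(cycles)))
  matrix(qd, nrow = length(cycles), dimnames = list(NULL, states))
}

#' Build the full transition matrix for one cycle
#'
#' Death is resolved first (background mortality at the cohort's current
#' age blended with state-specific disease mortality); event transitions
#' apply to survivors; the residual stays in state.  The `dead` row is the
#' identity row and cells not permitted by the model structure (e.g.
#' disabling stroke may move only to itself or death) are exactly zero.
#'
#' @param params A parameter set.
#' @param arm `"LVAD"` or `"MM"`.
#' @param cycle 0-based month index of the transition's starting cycle.
#' @param life_table Life table supplying background mortality.
#' @return A square matrix over [arm_states()] whose rows sum to 1.
#' @export
#' @examples
#' P <- build_transition_matrix(default_parameters(), "MM", 0)
#' rowSums(P)
build_transition_matrix <- function(params, arm = c("LVAD", "MM"), cycle,
                                    life_table = default_life_table()) {
  arm <- match.arg(arm)
  if (!is_scalar_number(cycle) || cycle < 0) abort("`cycle` must be >= 0")
  btt <- arm == "LVAD" && btt_enabled(params)
  states <- arm_states(arm, btt)
  alive <- setdiff(states, "dead")
  E <- event_flow_matrix(params, arm)
  qd <- drop(death_prob_matrix(params, arm, as.integer(cycle), life_table))
  P <- matrix(0, length(states), length(states), dimnames = list(states, states))
  P[alive, alive] <- (1 - qd) * E
  P[alive, "dead"] <- qd
  P["dead", "dead"] <- 1
  P
}
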