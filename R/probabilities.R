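# Probability plumbing shared by the cohort engine: period rescaling on the
# constant-hazard assumption, and combination of independent risks.

#' Rescale a probability to a different period length
#'
#' Converts a probability defined over one period to another assuming a
#' constant hazard within the period: `1 - (1 - p)^(to / from)`.  Used to
#' turn annual life-table and trial-interval risks into monthly cycle
#' probabilities.
#'
#' @param p Probability (vectorised) over a period of `from` months.
#' @param from,to Period lengths in months; both must be positive.
#' @return Probability over a period of `to` months.
#' @export
#' @examples
#' rescale_probability(0.3, from = 12, to = 1)
rescale_probability <- function(p, from, to) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be a probability in [0, 1]")
  }
  if (!is_scalar_number(from) || !is_scalar_number(to) || from <= 0 || to <= 0) {
    abort("`from` and `to` must be positive period lengths")
  }
  1 - (1 - p)^(to / from)
}

#' Combine background and disease mortality for one cycle
#'
#' Treats the two monthly probabilities as independent competing risks on the
#' hazard scale and returns the probability of dying from either:
#' `1 - (1 - background_p) * (1 - disease_p)`.
#'
#' @param background_p Monthly all-cause background mortality probability.
#' @param disease_p Monthly disease-specific mortality probability.
#' @return Combined monthly death probability (vectorised).
#' @export
#' @examples
#' blend_mortality(0.01, 0.05)
blend_mortality <- function(background_p, disease_p) {
  for (x in list(background_p, disease_p)) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
      abort("mortality probabilities must lie in [0, 1]")
    }
  }
  1 - (1 - background_p) * (1 - disease_p)
}
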