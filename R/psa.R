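# Probabilistic sensitivity analysis: seeded parameter sampling by
# method-of-moments distributions, per-draw model runs, and the
# cost-effectiveness acceptability curve via net monetary benefit.

# Method-of-moments samplers.  Means are the base-case values; spreads come
# from the PSA spec (`se` absolute or `rel_se` relative to the mean).
sample_family <- function(n, family, mean, se) {
  switch(family,
    fixed = rep(mean, n),
    beta = {
      if (mean <= 0 || mean >= 1) abort("beta family needs a mean in (0, 1)")
      v <- min(se^2, 0.95 * mean * (1 - mean)) # keep moments feasible
      nu <- mean * (1 - mean) / v - 1
      rbeta(n, mean * nu, (1 - mean) * nu)
    },
    gamma = {
      if (mean <= 0) abort("gamma family needs a positive mean")
      shape <- (mean / se)^2
      rgamma(n, shape = shape, rate = shape / mean)
    },
    lognormal = {
      if (mean <= 0) abort("lognormal family needs a positive mean")
      sdlog <- sqrt(log(1 + (se / mean)^2))
      rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
    },
    abort(sprintf("unknown distribution family '%s'", family))
  )
}

draw_psa_values <- function(params, n, seed, entries = params$psa$entries) {
  if (!length(entries)) abort("the parameter set has no PSA entries")
  if (!is_scalar_number(n) || n < 1) abort("`n` must be at least 1")
  cols <- withr::with_seed(seed, {
    lapply(entries, function(entry) {
      base <- param_get(params, entry$path)
      se <- entry$se %||% (entry$rel_se * base)
      sample_family(n, entry$family, base, se)
    })
  })
  names(cols) <- vapply(entries, `[[`, character(1), "path")
  tibble::as_tibble(cols)
}

apply_draw <- function(params, values) {
  for (path in names(values)) {
    params <- param_set(params, path, values[[path]])
  }
  params
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Samples every parameter listed in the set's `psa$entries` from its
#' distribution (beta for probabilities and utilities, gamma for costs,
#' lognormal for mortality multipliers, `fixed` for structural settings),
#' by method of moments around the base-case value.  Draws are reproducible
#' given the seed, and every draw satisfies the parameter-set invariants
#' (the beta and gamma families respect the bounds by construction).
#'
#' @param params A parameter set.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A list of `n` parameter sets.
#' @export
draw_psa_parameters <- function(params, n, seed = 1L) {
  values <- draw_psa_values(params, n, seed)
  purrr::map(seq_len(n), function(i) {
    validate_parameters(apply_draw(params, as.list(values[i, ])))
  })
}

#' Run the probabilistic sensitivity analysis
#'
#' Runs the full two-arm model once per parameter draw and collects per-draw
#' per-arm life years, QALYs and costs plus the incrementals.  The summary
#' reports means with 2.5%/97.5% percentile intervals (order statistics of
#' the draws), and two ICER summaries: the headline ratio of means (mean
#' incremental cost over mean incremental QALYs) and the mean of per-draw
#' ratios.
#'
#' @param params A parameter set.
#' @param n Number of draws.
#' @param seed Integer seed (reproducibility contract: identical inputs and
#'   seed give an identical result).
#' @param horizon Months, `Inf` for lifetime.
#' @param life_table Life table supplying background mortality.
#' @return A `lvad_psa` object with elements `draws` (tibble, one row per
#'   draw), `summary` (tibble), `icer_ratio_of_means`,
#'   `icer_mean_of_ratios`, `n`, `seed`.
#' @export
#' @examples
#' \donttest{
#' psa <- run_psa(default_parameters(), n = 100, seed = 7)
#' psa$icer_ratio_of_means
#' }
run_psa <- function(params, n = 1000, seed = 1L, horizon = Inf,
                    life_table = default_life_table()) {
  values <- draw_psa_values(params, n, seed)
  H <- resolve_horizon(params, horizon)
  rows <- purrr::map(seq_len(n), function(i) {
    p_i <- apply_draw(params, as.list(values[i, ]))
    lvad <- tryCatch(run_arm(p_i, "LVAD", H, life_table),
                     error = function(e) abort(sprintf("PSA draw %d failed: %s",
                                                       i, conditionMessage(e))))
    mm <- run_arm(p_i, "MM", H, life_table)
    tibble::tibble(draw = i, mm_ly = mm$ly, mm_qaly = mm$qaly, mm_cost = mm$cost,
                   lvad_ly = lvad$ly, lvad_qaly = lvad$qaly, lvad_cost = lvad$cost,
                   inc_ly = lvad$ly - mm$ly, inc_qaly = lvad$qaly - mm$qaly,
                   inc_cost = lvad$cost - mm$cost)
  })
  draws <- dplyr::bind_rows(rows)
  metrics <- setdiff(names(draws), "draw")
  summary <- purrr::map_dfr(metrics, function(m) {
    x <- draws[[m]]
    tibble::tibble(metric = m, mean = mean(x),
                   lo = unname(quantile(x, 0.025, type = 1)),
                   hi = unname(quantile(x, 0.975, type = 1)))
  })
  structure(list(draws = draws, summary = summary,
                 icer_ratio_of_means = mean(draws$inc_cost) / mean(draws$inc_qaly),
                 icer_mean_of_ratios = mean(draws$inc_cost / draws$inc_qaly),
                 n = n, seed = seed, horizon = H),
            class = "lvad_psa")
}

#' @export
print.lvad_psa <- function(x, ...) {
  cat(sprintf("<lvad_psa: %d draws, seed %s, %d cycles>\n", x$n, x$seed, x$horizon))
  print(x$summary, n = Inf)
  cat(sprintf("ICER (ratio of means) £%s/QALY\n",
              format(round(x$icer_ratio_of_means), big.mark = ",")))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda` on the grid, the probability
#' of cost-effectiveness is the fraction of PSA draws with positive
#' incremental net monetary benefit `lambda * inc_qaly - inc_cost` (strict
#' inequality at zero).  The net-benefit formulation is robust to draws
#' with negative incremental QALYs.
#'
#' @param psa A `lvad_psa` object, or a data frame of draws with columns
#'   `inc_qaly` and `inc_cost`.
#' @param wtp_grid Willingness-to-pay values in GBP per QALY.
#' @return A `lvad_ceac` tibble with columns `wtp` and `probability`.
#' @export
compute_ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  draws <- if (inherits(psa, "lvad_psa")) psa$draws else tibble::as_tibble(psa)
  if (!nrow(draws)) abort("PSA has no draws")
  if (!length(wtp_grid)) abort("`wtp_grid` must be non-empty")
  prob <- vapply(wtp_grid, function(wtp) {
    mean(wtp * draws$inc_qaly - draws$inc_cost > 0)
  }, numeric(1))
  out <- tibble::tibble(wtp = wtp_grid, probability = prob)
  class(out) <- c("lvad_ceac", class(out))
  out
}

#' Export a CEAC to delimited text
#'
#' @param ceac A `lvad_ceac` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(ceac, path) {
  write.csv(ceac, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
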