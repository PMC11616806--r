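test_that("fixed families reproduce the base case in every draw", {
  p <- toy_params(lvad_q = 0.05, mm_q = 0.1, lvad_u = 0.7, mm_u = 0.5,
                  psa_entries = list(
                    list(path = "utilities.lvad_baseline", family = "fixed"),
                    list(path = "costs.device", family = "fixed")))
  draws <- draw_psa_parameters(p, n = 4, seed = 9)
  expect_length(draws, 4)
  for (d in draws) {
    expect_equal(d$utilities$lvad_baseline, p$utilities$lvad_baseline)
    expect_equal(d$costs$device, p$costs$device)
  }
})

test_that("identical seeds give identical draw sequences and PSA results", {
  p <- default_parameters()
  d1 <- draw_psa_parameters(p, n = 3, seed = 123)
  d2 <- draw_psa_parameters(p, n = 3, seed = 123)
  expect_identical(d1, d2)
  expect_false(identical(d1, draw_psa_parameters(p, n = 3, seed = 124)))
  psa1 <- run_psa(p, n = 5, seed = 77, horizon = 60)
  psa2 <- run_psa(p, n = 5, seed = 77, horizon = 60)
  expect_identical(psa1$draws, psa2$draws)
  expect_identical(psa1$summary, psa2$summary)
})

test_that("beta sampling recovers the requested mean", {
  p <- toy_params(mm_u = 0.6,
                  psa_entries = list(
                    list(path = "utilities.mm_baseline", family = "beta",
                         rel_se = 0.1)))
  draws <- draw_psa_parameters(p, n = 2000, seed = 5)
  x <- vapply(draws, function(d) d$utilities$mm_baseline, numeric(1))
  se <- 0.06 / sqrt(2000)
  expect_lt(abs(mean(x) - 0.6), 3 * se)
  expect_true(all(x > 0 & x < 1))
})

test_that("a single fixed draw matches the deterministic model", {
  p <- default_parameters()
  p$psa$entries <- list(list(path = "costs.device", family = "fixed"))
  p <- validate_parameters(p)
  psa <- run_psa(p, n = 1, seed = 1, horizon = 60)
  lvad <- run_arm(p, "LVAD", 60)
  mm <- run_arm(p, "MM", 60)
  expect_equal(psa$draws$lvad_qaly, lvad$qaly, tolerance = 1e-12)
  expect_equal(psa$draws$mm_cost, mm$cost, tolerance = 1e-12)
  expect_equal(psa$icer_ratio_of_means,
               (lvad$cost - mm$cost) / (lvad$qaly - mm$qaly), tolerance = 1e-12)
})

test_that("PSA summaries are the moments and order statistics of the draws", {
  psa <- run_psa(default_parameters(), n = 40, seed = 21, horizon = 60)
  for (m in psa$summary$metric) {
    x <- psa$draws[[m]]
    row <- psa$summary[psa$summary$metric == m, ]
    expect_equal(row$mean, mean(x))
    expect_equal(row$lo, unname(quantile(x, 0.025, type = 1)))
    expect_equal(row$hi, unname(quantile(x, 0.975, type = 1)))
  }
})

test_that("the CEAC is the net-benefit exceedance fraction", {
  draws <- tibble::tibble(inc_qaly = c(1, 1), inc_cost = c(40000, 60000))
  ceac <- compute_ceac(draws, wtp_grid = c(30000, 50000, 70000))
  expect_equal(ceac$probability, c(0, 0.5, 1))
  # strict inequality at zero net benefit
  expect_equal(compute_ceac(tibble::tibble(inc_qaly = 1, inc_cost = 50000),
                            wtp_grid = 50000)$probability, 0)
  expect_error(compute_ceac(tibble::tibble(inc_qaly = numeric(), inc_cost = numeric())),
               "no draws")
  expect_error(compute_ceac(draws, wtp_grid = numeric()), "non-empty")
})

test_that("the CEAC is monotone in willingness to pay when gains are positive", {
  psa <- run_psa(default_parameters(), n = 60, seed = 11, horizon = 120)
  expect_true(all(psa$draws$inc_qaly > 0))
  ceac <- compute_ceac(psa, seq(0, 100000, by = 5000))
  expect_true(all(diff(ceac$probability) >= 0))
  expect_true(all(ceac$probability >= 0 & ceac$probability <= 1))
})

test_that("unknown specifications are refused", {
  p <- toy_params(psa_entries = list(
    list(path = "utilities.mm_baseline", family = "beta", rel_se = 0.1)))
  p$psa$entries[[1]]$path <- "not.a.path"
  expect_error(validate_parameters(p), "does not resolve")
  expect_error(run_psa(toy_params(), n = 10, seed = 1), "no PSA entries")
})
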