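test_that("a constant-hazard cohort decays geometrically", {
  p <- toy_params(lvad_q = 0.1)
  tr <- run_cohort(p, "LVAD", horizon = 2, life_table = flat_life_table(0))
  expect_equal(unname(unclass(tr)[, "dt"]), c(1, 0.9, 0.81), tolerance = 1e-12)
})

test_that("with zero risks the cohort never leaves the starting state", {
  p <- toy_params()
  tr <- run_cohort(p, "MM", horizon = 24, life_table = flat_life_table(0))
  expect_equal(unname(unclass(tr)[, "mm"]), rep(1, 25))
  expect_equal(unname(unclass(tr)[, "dead"]), rep(0, 25))
})

test_that("undiscounted mean survival matches the geometric closed form", {
  # constant monthly death p: expected alive-months sum to (1 - p) / p;
  # truncation at the age cap is negligible at p = 0.1
  p <- toy_params(lvad_q = 0.1)
  res <- run_arm(p, "LVAD", horizon = "lifetime", life_table = flat_life_table(0))
  expect_equal(res$ly * 12, 0.9 / 0.1, tolerance = 1e-3)
  expect_equal(res$qaly, res$ly, tolerance = 1e-12) # utility 1, no decrements
})

test_that("twelve alive cycles at utility one accrue one undiscounted LY and QALY", {
  p <- toy_params()
  res <- run_arm(p, "LVAD", horizon = 12, life_table = flat_life_table(0))
  expect_equal(res$ly, 1)
  expect_equal(res$qaly, 1)
  expect_equal(res$cost, 0)
})

test_that("a cycle's cost contribution carries the (1+r)^(-t/12) factor", {
  p <- toy_params(outpatient_lvad = 500, discount = 0.035)
  lt <- flat_life_table(0)
  tr <- run_cohort(p, "LVAD", horizon = 12, life_table = lt)
  pay <- cycle_payoffs(p, "LVAD")
  c12 <- accumulate_outcomes(tr, pay, horizon = 12)$cost
  c11 <- accumulate_outcomes(tr, pay, horizon = 11)$cost
  expect_equal(c12 - c11, 500 / 1.035, tolerance = 1e-10)
  expect_equal(c12, 500 * sum(1.035^(-(1:12) / 12)), tolerance = 1e-10)
})

test_that("an immediately extinct cohort accrues nothing", {
  p <- toy_params(mm_q = 1, outpatient_mm = 1000)
  res <- run_arm(p, "MM", horizon = 24, life_table = flat_life_table(0))
  expect_equal(res$ly, 0)
  expect_equal(res$qaly, 0)
  expect_equal(res$cost, 0) # no state costs accrue after death, no one-offs here
  expect_equal(unname(res$cumulative_deaths["cycle_24"]), 1)
})

test_that("the implant bundle is charged once, undiscounted, at entry", {
  p <- toy_params(mm_q = 1, device = 100000, discount = 0.1)
  res <- run_arm(p, "LVAD", horizon = 12, life_table = flat_life_table(0))
  expect_equal(res$cost, 100000)
})

test_that("event one-off costs are charged on state inflows", {
  # dt -> ds flow of 0.2 in cycle 1 with a £10,000 episode cost, no discount
  p <- toy_params(ds = 0.2)
  p$costs$event_oneoff$ds <- 10000
  p <- validate_parameters(p)
  res <- run_arm(p, "LVAD", horizon = 1, life_table = flat_life_table(0))
  expect_equal(res$cost, 0.2 * 10000, tolerance = 1e-12)
})

test_that("complication load reduces QALYs only in the cycle of occurrence", {
  none <- list(prob = 0, cost = 0, decrement = 0)
  comp <- list(gib = list(prob = 0.1, cost = 3000, decrement = 0.2),
               mm_readmission = none)
  p <- toy_params(lvad_u = 0.8, complications = comp)
  res <- run_arm(p, "LVAD", horizon = 12, life_table = flat_life_table(0))
  expect_equal(res$qaly, (0.8 - 0.1 * 0.2) * 12 / 12, tolerance = 1e-12)
  expect_equal(res$cost, 0.1 * 3000 * 12, tolerance = 1e-12)
  # MM readmission is cost-only
  comp2 <- list(gib = none, mm_readmission = list(prob = 0.1, cost = 2000, decrement = 0))
  p2 <- toy_params(mm_u = 0.6, complications = comp2)
  res2 <- run_arm(p2, "MM", horizon = 12, life_table = flat_life_table(0))
  expect_equal(res2$qaly, 0.6, tolerance = 1e-12)
  expect_equal(res2$cost, 0.1 * 2000 * 12, tolerance = 1e-12)
})

test_that("the fast cohort path agrees with explicit matrix products", {
  p <- default_parameters()
  for (arm in c("LVAD", "MM")) {
    tr <- run_cohort(p, arm, horizon = 12)
    states <- attr(tr, "states")
    v <- numeric(length(states)); names(v) <- states
    v[if (arm == "LVAD") "dt" else "mm"] <- 1
    for (t in 0:11) {
      v <- drop(v %*% build_transition_matrix(p, arm, t))
      expect_equal(unclass(tr)[t + 2L, ], v, tolerance = 1e-12)
    }
  }
})

test_that("occupancy conserves mass and death is monotone on the defaults", {
  p <- default_parameters()
  for (arm in c("LVAD", "MM")) {
    tr <- run_cohort(p, arm, horizon = 60)
    expect_equal(unname(rowSums(unclass(tr))), rep(1, 61), tolerance = 1e-9)
    expect_true(all(diff(unclass(tr)[, "dead"]) >= -1e-15))
  }
})

test_that("discounted totals fall as the discount rate rises", {
  p <- default_parameters()
  tr <- run_cohort(p, "LVAD", horizon = 120)
  pay <- cycle_payoffs(p, "LVAD")
  res <- lapply(c(0, 0.035, 0.1), function(r) accumulate_outcomes(tr, pay, r))
  for (f in c("ly", "qaly", "cost")) {
    vals <- vapply(res, `[[`, numeric(1), f)
    expect_true(all(diff(vals) < 0))
  }
})

test_that("horizon totals nest: 2-year <= 5-year <= lifetime", {
  p <- default_parameters()
  for (arm in c("LVAD", "MM")) {
    tr <- run_cohort(p, arm, "lifetime")
    pay <- cycle_payoffs(p, arm)
    r24 <- accumulate_outcomes(tr, pay, horizon = 24)
    r60 <- accumulate_outcomes(tr, pay, horizon = 60)
    rl <- accumulate_outcomes(tr, pay)
    for (f in c("ly", "qaly", "cost")) {
      expect_lte(r24[[f]], r60[[f]])
      expect_lte(r60[[f]], rl[[f]])
    }
    expect_lte(rl$qaly, rl$ly)
  }
})

test_that("traces export tidily with cycle and cumulative-death columns", {
  tr <- run_cohort(default_parameters(), "MM", horizon = 6)
  tb <- tibble::as_tibble(tr)
  expect_equal(tb$cycle, 0:6)
  expect_equal(tb$cumulative_deaths, tb$dead)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  reread <- read.csv(path)
  expect_equal(nrow(reread), 7)
  expect_true(all(c("cycle", "mm", "dead", "cumulative_deaths") %in% names(reread)))
})
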