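arm_stub <- function(ly, qaly, cost, horizon = 540, discount = 0.035) {
  list(ly = ly, qaly = qaly, cost = cost, horizon = horizon,
       annual_discount = discount)
}

test_that("incremental analysis reproduces the published lifetime arithmetic", {
  cea <- incremental_analysis(arm_stub(4.65, 3.32, 171621),
                              arm_stub(0.92, 0.46, 18886))
  expect_equal(cea$inc_cost, 152735)
  expect_equal(cea$inc_qaly, 2.86, tolerance = 1e-12)
  expect_equal(cea$inc_ly, 3.73, tolerance = 1e-12)
  expect_equal(cea$icer_per_qaly, 152735 / 2.86, tolerance = 1e-12)
  expect_equal(cea$dominance, "none")
})

test_that("identical arms yield zero incrementals and undefined ICERs", {
  a <- arm_stub(2, 1.5, 50000)
  cea <- incremental_analysis(a, a)
  expect_equal(cea$inc_cost, 0)
  expect_equal(cea$inc_qaly, 0)
  expect_true(is.na(cea$icer_per_qaly))
  expect_true(is.na(cea$icer_per_ly))
})

test_that("dominance is flagged and suppresses the ICER", {
  cheaper_better <- incremental_analysis(arm_stub(3, 2, 10000),
                                         arm_stub(1, 1, 20000))
  expect_equal(cheaper_better$dominance, "intervention_dominates")
  expect_true(is.na(cheaper_better$icer_per_qaly))
  dearer_worse <- incremental_analysis(arm_stub(1, 1, 30000),
                                       arm_stub(3, 2, 10000))
  expect_equal(dearer_worse$dominance, "comparator_dominates")
  expect_true(is.na(dearer_worse$icer_per_qaly))
})

test_that("incremental analysis is antisymmetric in its arms", {
  withr::with_seed(42, {
    for (i in 1:25) {
      a <- arm_stub(runif(1, 0, 6), runif(1, 0, 4), runif(1, 0, 2e5))
      b <- arm_stub(runif(1, 0, 6), runif(1, 0, 4), runif(1, 0, 2e5))
      ab <- incremental_analysis(a, b)
      ba <- incremental_analysis(b, a)
      expect_equal(ab$inc_ly, -ba$inc_ly)
      expect_equal(ab$inc_qaly, -ba$inc_qaly)
      expect_equal(ab$inc_cost, -ba$inc_cost)
    }
  })
})

test_that("mismatched settings are refused", {
  expect_error(incremental_analysis(arm_stub(2, 1, 1e4, horizon = 24),
                                    arm_stub(1, 0.5, 1e4, horizon = 60)),
               "different horizons")
  expect_error(incremental_analysis(arm_stub(2, 1, 1e4, discount = 0),
                                    arm_stub(1, 0.5, 1e4, discount = 0.035)),
               "different discount")
})

test_that("QALY shortfall follows the published definition", {
  sf <- qaly_shortfall(0.46, 10.84)
  expect_equal(sf$absolute, 10.38, tolerance = 1e-12)
  expect_equal(sf$proportional, 10.38 / 10.84, tolerance = 1e-12)
  expect_equal(round(sf$proportional, 2), 0.96)
  expect_equal(unlist(qaly_shortfall(3, 3)), c(absolute = 0, proportional = 0))
  expect_equal(unlist(qaly_shortfall(0, 7)), c(absolute = 7, proportional = 1))
  expect_error(qaly_shortfall(0.5, 0), "positive")
  expect_error(qaly_shortfall(-1, 5), "non-negative")
})

test_that("severity weights follow the cutoff table with inclusive bounds", {
  expect_equal(severity_weight(10.38, 0.96), 1.7)
  expect_equal(severity_weight(5, 0.5), 1.0)
  expect_equal(severity_weight(18, 0.5), 1.7) # boundary is inclusive
  expect_equal(severity_weight(12, 0.5), 1.2)
  expect_equal(severity_weight(1, 0.85), 1.2)
  expect_equal(severity_weight(1, 0.95), 1.7)
  # monotone non-decreasing in both arguments
  grid <- expand.grid(a = c(0, 5, 12, 18, 25), p = c(0, 0.5, 0.85, 0.95, 1))
  w <- mapply(severity_weight, grid$a, grid$p)
  for (i in seq_len(nrow(grid))) {
    higher <- grid$a >= grid$a[i] & grid$p >= grid$p[i]
    expect_true(all(w[higher] >= w[i]))
  }
  # a configurable single-cutoff table (proportional 0.70) is honoured
  nl <- tibble::tibble(weight = c(1.5, 1), absolute_min = c(Inf, 0),
                       proportional_min = c(0.70, 0))
  expect_equal(severity_weight(1, 0.75, nl), 1.5)
  expect_equal(severity_weight(1, 0.5, nl), 1.0)
  expect_error(severity_weight(1, 0.5, tibble::tibble(weight = 1)), "cutoffs")
})

test_that("weighted ICERs divide by the modifier and round to pounds", {
  expect_equal(weighted_icer(53496, 1.7), 31468)
  expect_equal(weighted_icer(100000, 1.2), 83333)
  expect_equal(weighted_icer(42000, 1.0), 42000)
  expect_equal(weighted_icer(53496, 1.7, round = FALSE), 53496 / 1.7)
  for (w in c(1, 1.2, 1.7)) expect_lte(weighted_icer(53496, w), 53496)
  expect_error(weighted_icer(1000, 0), "positive")
  expect_error(weighted_icer(1000, 0.5), "below 1")
})

test_that("run_cea assembles per-horizon tables and the severity layer", {
  p <- default_parameters()
  cea <- run_cea(p, horizons = c(24, Inf), genpop_qalys = 10.84)
  expect_named(cea$horizons, c("24m", "lifetime"))
  td <- tidy(cea)
  expect_setequal(unique(td$horizon), c("24m", "lifetime"))
  life <- cea$horizons$lifetime
  expect_equal(life$cea$inc_cost, life$lvad$cost - life$mm$cost)
  expect_equal(cea$shortfall$weight,
               severity_weight(cea$shortfall$absolute, cea$shortfall$proportional))
  expect_equal(cea$shortfall$weighted_icer,
               weighted_icer(life$cea$icer_per_qaly, cea$shortfall$weight))
  g <- glance(cea)
  expect_equal(g$icer_per_qaly, life$cea$icer_per_qaly)
  expect_equal(g$weight, cea$shortfall$weight)
})
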