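test_that("loading fills population and discounting defaults", {
  raw <- unclass(toy_params())
  raw$population <- NULL
  raw$discounting <- NULL
  p <- load_parameters(yaml::as.yaml(raw, precision = 15))
  expect_equal(p$population$start_age, 65)
  expect_equal(p$population$female_fraction, 0.5)
  expect_equal(p$discounting$annual_discount, 0.035)
  expect_equal(p$population$age_cap, 110)
})

test_that("range violations are reported with their dotted paths", {
  raw <- unclass(toy_params())
  raw$utilities$mm_baseline <- 1.2
  raw$events$nds <- -0.1
  err <- expect_error(load_parameters(yaml::as.yaml(raw, precision = 15)))
  expect_match(conditionMessage(err), "utilities.mm_baseline")
  expect_match(conditionMessage(err), "events.nds")
})

test_that("an empty document lists every missing required section", {
  err <- expect_error(load_parameters("{}"))
  for (path in c("mortality.lvad_monthly", "mortality.mm_monthly",
                 "events", "complications", "costs", "utilities")) {
    expect_match(conditionMessage(err), path, fixed = TRUE)
  }
  expect_error(load_parameters("nonsense_section: {a: 1}"), "unknown configuration")
})

test_that("a short mortality schedule is rejected", {
  raw <- unclass(toy_params())
  raw$mortality$mm_monthly <- rep(0.1, 12)
  expect_error(load_parameters(yaml::as.yaml(raw, precision = 15)),
               "at least 24")
})

test_that("parameter sets survive a YAML round trip", {
  p <- generate_parameter_set(synthetic_spec(seed = 11))
  p2 <- load_parameters(as_config_yaml(p))
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-10)
  # and serialising the reloaded set reproduces the same document
  expect_identical(as_config_yaml(p2), as_config_yaml(load_parameters(as_config_yaml(p2))))
})

test_that("dotted-path access reads and writes leaves", {
  p <- toy_params()
  expect_equal(param_get(p, "utilities.lvad_baseline"), 1)
  p2 <- param_set(p, "utilities.lvad_baseline", 0.7)
  expect_equal(param_get(p2, "utilities.lvad_baseline"), 0.7)
  expect_equal(param_get(p, "utilities.lvad_baseline"), 1) # input untouched
  expect_error(param_get(p, "utilities.bogus"), "unknown parameter path")
  expect_error(param_set(p, "no.such.leaf", 1), "unknown parameter path")
})

test_that("named scenario application is idempotent and leaves the base intact", {
  base <- default_parameters()
  once <- apply_scenario(base, "intermacs1")
  twice <- apply_scenario(once, "intermacs1")
  expect_identical(unclass(twice), unclass(once))
  expect_identical(attr(twice, "scenarios_applied"), "intermacs1")
  expect_equal(attr(base, "scenarios_applied"), character())
  # direction: lower INTERMACS profile, lower utilities, higher mortality
  expect_lt(once$utilities$lvad_baseline, base$utilities$lvad_baseline)
  expect_lt(once$utilities$mm_baseline, base$utilities$mm_baseline)
  expect_gt(once$mortality$lvad_multiplier, base$mortality$lvad_multiplier)
  expect_gt(once$mortality$mm_multiplier, base$mortality$mm_multiplier)
})

test_that("empty and ad-hoc overrides behave as documented", {
  base <- default_parameters()
  noop <- apply_scenario(base, scenario_override("noop"))
  expect_equal(unclass(noop), unclass(base), ignore_attr = TRUE)
  sc <- scenario_override("dearer_device", scale = list("costs.device" = 1.5))
  p1 <- apply_scenario(base, sc)
  expect_equal(p1$costs$device, base$costs$device * 1.5)
  expect_identical(unclass(apply_scenario(p1, sc)), unclass(p1))
  expect_error(apply_scenario(base, "unheard_of"), "unknown scenario")
  expect_error(apply_scenario(base, scenario_override("bad", set = list("x.y" = 1))),
               "unknown parameter path")
  expect_error(apply_scenario(base, scenario_override("invalid",
                                                      set = list("utilities.mm_baseline" = 2))),
               "utilities.mm_baseline")
})

test_that("the bridge-to-transplant scenario activates the BTT/HT states", {
  p <- apply_scenario(default_parameters(), "btt")
  expect_equal(p$events$btt, 0.006)
  expect_equal(p$events$ht, 0.028)
  expect_true(all(c("btt", "ht") %in% arm_states("LVAD", btt_enabled = TRUE)))
  P <- build_transition_matrix(p, "LVAD", cycle = 0)
  expect_true(P["dt", "btt"] > 0)
  expect_true(P["btt", "ht"] > 0)
})

test_that("the shipped default configuration matches the generated defaults", {
  path <- system.file("extdata", "default_config.yaml", package = "lvadcea")
  shipped <- load_parameters(path)
  expect_equal(unclass(shipped), unclass(default_parameters()), tolerance = 1e-9)
  res <- run_arm(shipped, "MM", 24)
  expect_lte(abs(unname(res$cumulative_deaths["cycle_24"]) - 0.91), 0.005)
})
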