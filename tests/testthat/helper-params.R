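# Hand-built fixtures: a minimal valid parameter set with everything off by
# default (so individual mechanisms can be switched on in isolation), a
# flat life table, and randomized generator specs for property suites.

toy_params <- function(lvad_q = 0, mm_q = 0,
                       nds = 0, ds = 0, rhf = 0, ar = 0,
                       mm_nds = 0, mm_ds = 0,
                       lvad_u = 1, mm_u = 1,
                       decrements = list(nds = 0, ds = 0, rhf = 0, ar = 0),
                       event_multipliers = list(dt = 1, nds = 1, ds = 1, rhf = 1,
                                                ar = 1, mm = 1, btt = 1, ht = 1),
                       outpatient_lvad = 0, outpatient_mm = 0, device = 0,
                       discount = 0, start_age = 65, age_cap = 110,
                       complications = NULL, psa_entries = list()) {
  none <- list(prob = 0, cost = 0, decrement = 0)
  validate_parameters(list(
    population = list(start_age = start_age, female_fraction = 0.5,
                      age_cap = age_cap, cohort_size = 1000),
    discounting = list(annual_discount = discount),
    mortality = list(lvad_monthly = rep(lvad_q, 24), mm_monthly = rep(mm_q, 24),
                     lvad_multiplier = 1, mm_multiplier = 1,
                     event_multipliers = event_multipliers),
    events = list(nds = nds, ds = ds, rhf = rhf, ar = ar,
                  mm_nds = mm_nds, mm_ds = mm_ds, btt = 0, ht = 0),
    complications = complications %||% list(gib = none, mm_readmission = none),
    costs = list(device = device, implant_op = 0, icu_day = 0, icu_days = 0,
                 ward_day = 0, ward_days = 0,
                 event_oneoff = list(nds = 0, ds = 0, rhf = 0, ar = 0, ht = 0),
                 state_monthly = list(nds = 0, ds = 0, rhf = 0, ar = 0),
                 outpatient_lvad_monthly = outpatient_lvad,
                 outpatient_mm_monthly = outpatient_mm,
                 ht_monthly = 0),
    utilities = list(lvad_baseline = lvad_u, mm_baseline = mm_u, ht = 0.74,
                     decrements = decrements),
    psa = list(entries = psa_entries),
    scenarios = list()))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Flat life table: constant annual background mortality (0 allowed, for
# isolating disease mortality in engine tests).
flat_life_table <- function(q = 0) {
  dplyr::bind_rows(
    tibble::tibble(age = 0:110, sex = "F", annual_death_prob = q),
    tibble::tibble(age = 0:110, sex = "M", annual_death_prob = q))
}

# Randomized generator spec for property suites: death targets drawn within
# broad plausible bands, no lifetime anchors (base utilities/costs used).
random_spec <- function(seed) {
  targets <- withr::with_seed(seed, c(runif(1, 0.5, 0.95), runif(1, 0.05, 0.4)))
  synthetic_spec(seed = seed,
                 mm_death_2yr = targets[1], lvad_death_2yr = targets[2],
                 lifetime_qaly_targets = NULL, lifetime_cost_targets = NULL)
}
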