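---
title: "Methods: the LVAD destination-therapy cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LVAD destination-therapy cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvadcea)
```

This vignette is the package's own account of its model: the structure and
its assumptions, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the design decisions taken where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## Decision problem and model structure

The package compares permanent LVAD implantation (destination therapy)
with optimal medical management in advanced heart failure patients who are
ineligible for heart transplant, from a UK healthcare perspective. Because
the life-expectancy impact is large, a cohort state-transition (Markov)
model in monthly cycles is used rather than a decision tree.

Health states separate "alive without a major event" from the major-event
states — non-disabling stroke, disabling stroke, right heart failure (RHF)
and aortic regurgitation (AR) for the device arm; the two stroke states
for the medical arm — because these events carry substantially increased
mortality and permanent quality-of-life loss. A patient's state is the
*worst* event experienced, with severity order

> disabling stroke > RHF > AR > non-disabling stroke,

so transitions run only toward more severe states (e.g. RHF may progress
to disabling stroke but not revert), and disabling stroke is exited only
through death. Complications — GI bleeding, device failure, driveline
infection, pump infection, pump exchange, arrhythmia for the device arm;
all-cause readmission for the medical arm — are *not* states: they are
memoryless per-cycle Bernoulli events layered on alive states, adding
expected cost and a utility decrement confined to the cycle of occurrence.
This matches how such events are reported (episode rates) and keeps the
state space small.

## Transition mechanics

The published sources report marginal monthly probabilities, which do not
by themselves define a transition matrix. The engine therefore fixes a
competing-risk convention:

1. **Death first.** Each cycle's state-specific death probability blends
   background and disease mortality on the survival scale,
   `q = 1 − (1 − q_bg)(1 − q_dis · m_s)`, where `m_s` is the state's
   mortality multiplier (how the "adjusted for death due to a major event"
   step is operationalised — a multiplicative hazard-scale choice the
   sources leave open; the multipliers are ordinary config fields).
2. **Events among survivors.** Permitted event transitions receive
   `(1 − q) · p_event`; the residual stays in state.

Because the event probabilities are cycle-constant while death
probabilities vary with age and month, the cycle-`t` matrix factorises as
`P_t = diag(1 − q_t) E + q_t e_dead` with a constant survivor-flow matrix
`E`; the engine propagates occupancy with this factorisation (a few
microseconds per cycle), and `build_transition_matrix()` exposes the full
matrix for inspection and testing. Rows sum to one to 1e-12 and forbidden
cells are exactly zero; the test suite verifies the fast path against
explicit matrix products and against an independent individual-level
simulation (100,000 patients) written directly from the convention above.

Background mortality comes from an age-and-sex life table: annual
probabilities are rescaled to monthly on the constant-hazard assumption
(`1 − (1 − p)^(1/12)`), sexes are mixed with the female fraction (0.5 by
default) as a static weight, age advances 1/12 year per cycle, and the
age cap of 110 years (life-table probability 1) defines the lifetime
horizon of `(110 − 65) × 12 = 540` cycles. Disease-specific mortality is a
24-value monthly schedule per arm; beyond month 24 the month-24 risk is
held constant for all remaining cycles — deliberately conservative
relative to extrapolating the late downward trend, and the single choice
that most distinguishes this model from earlier UK analyses.

## Outcome accumulation

At cycle `t ≥ 1` the discount factor `(1 + r)^(−t/12)` (annual rate
`r = 0.035`) multiplies:

- life years: 1/12 per alive person-cycle (end-of-cycle occupancy);
- QALYs: state utility — arm baseline minus the permanent decrement of the
  occupied event state, floored at 0 — minus the expected one-cycle
  complication decrement, divided by 12;
- costs: monthly state costs (arm outpatient cost plus event-state
  excess), expected complication costs, and one-off episode costs charged
  on the *inflow* mass entering an event state that cycle.

The implant bundle (device price, operation, ICU and ward days) is charged
undiscounted at cycle 0 as the cost of entering the device arm. **No
half-cycle correction** is applied: with monthly cycles the correction is
second-order (below 1/24 of a cycle's payoff) and far inside the parameter
uncertainty; omitting it keeps every accumulated quantity an exact linear
functional of the trace, which the calibration below exploits.

Death fractions are read off the trace at cycles 24 and 60 and at horizon
end, matching the 2-year/5-year/lifetime reporting convention. The
medical-arm readmission complication carries cost only (no decrement) by
default — the sources do not state a utility effect — and the config can
add one.

## The synthetic parameter set

The analysis this package implements rests on a supplementary parameter
file that is not publicly deposited. Rather than inventing numbers ad hoc
in tests, the package ships a *generator* (`generate_parameter_set()`)
whose defaults are the packaged study conditions (`default_parameters()`).
It is structurally faithful to what the main text states:

- **Mortality.** The LVAD monthly disease-mortality schedule declines over
  months 1–24 (shape `1 + e^{−(m−1)/4}`: the month-1 hazard is twice the
  frozen month-24 level, emulating perioperative risk) and the MM schedule
  is constant. Each schedule's level is solved by one-dimensional root
  finding *against the cohort engine itself* so that two-year cumulative
  deaths hit the published anchors: 91% (MM) and 25% (LVAD). The root
  finder sees the full model — background mortality, event states with
  their multipliers — so the calibration is exact by construction (the
  acceptance suite checks ±0.005).
- **Utilities and costs.** Baseline utilities (one per arm) and monthly
  outpatient costs enter the discounted totals linearly once mortality is
  fixed, so they are anchored by exact linear solves to the published
  deterministic lifetime per-arm totals: QALYs 0.46 (MM) and 3.32 (LVAD);
  costs £18,886 and £171,621. The device price default (£109,140) is the
  published UK figure; the remaining implant-bundle, episode and
  complication magnitudes are synthetic values in clinically plausible
  ranges, drawn once per seed.
- **Event/complication probabilities** are drawn uniformly within monthly
  ranges consistent with the trial literature's order of magnitude
  (strokes and RHF a few per thousand per month; GI bleeding 1–2% per
  month; readmission ~10% per month for inotrope-dependent medical
  patients).

What the generator does **not** emulate: the actual supplementary values,
real ONS life-table numbers or NHS reference costs, correlations between
parameters, or time-varying complication rates. Passing tests therefore
demonstrate that the *machinery* reproduces the published result structure
under faithfully calibrated conditions — not that the package re-derives
the published numbers from primary data.

With these anchors the deterministic lifetime comparison gives incremental
cost £152,735 and incremental QALYs 2.86 — the published incrementals —
and hence an ICER of £53,404/QALY (the ratio of the anchored full-precision
values; the published £53,496 was formed from *its* unpublished
full-precision inputs, which printed rounding cannot recover). Life years
per arm are left free; they land where the calibrated mortality puts them.

## Severity weighting

The shortfall layer follows the current UK appraisal framework: absolute
shortfall = general-population remaining QALYs minus comparator QALYs;
proportional = absolute / general-population QALYs; the weight is the
highest of {1.7, 1.2, 1.0} whose absolute **or** proportional cutoff
(18 / 0.95, 12 / 0.85, inclusive boundaries) is met; the weighted ICER
divides by the weight. The general-population value is a user input
(externally calculated in practice; 10.84 reproduces the published
shortfall pair 10.38 / 0.96). The cutoff table is data, not code, so the
single-cutoff variant used elsewhere in Europe (proportional 0.70) can be
explored by passing a different table.

## Uncertainty analysis

**One-way (tornado).** Each listed parameter is set to its low and high
value with everything else at base, and the lifetime ICER is recorded;
entries sort by ICER-range width. Only one-way variation is provided. The
default ranges put a deliberately wide band on the two ongoing outpatient
costs (the literature spread) and ±20–25% bands elsewhere.

**Probabilistic.** Parameters listed in the config's `psa` section are
sampled independently (a joint-draw hook can replace the value table) by
method of moments around the base value: beta for probabilities and
utilities, gamma for costs, lognormal for the two arm-level mortality
multipliers, `fixed` for structure. The published analysis does not state
its families or spreads; the relative standard errors shipped here
(utilities 4–5%, mortality multipliers 6%, device price 7%, outpatient
costs 12%, event/complication probabilities 20%) were chosen once so the
resulting interval widths are of the order of the published probabilistic
table, and are documented config fields. Each draw reruns the full
two-arm lifetime model; summaries report means and 2.5/97.5 percentile
*order statistics*, and the headline probabilistic ICER is the ratio of
means (mean incremental cost over mean incremental QALYs), with the mean
of per-draw ratios also exposed.

**CEAC.** The probability of cost-effectiveness at willingness-to-pay
`λ` is the fraction of draws with positive incremental net monetary
benefit `λ·ΔQ − ΔC` (strict inequality at 0) — well-defined even for
draws with negative incremental QALYs, unlike ICER ordering. The default
grid is £0–100,000 in £1,000 steps.

## Scenarios and subgroups

Named overrides replace (`set`) or rescale (`scale`) dotted parameter
paths and are validated like base values. Because overrides may be
multiplicative, idempotence is enforced by name: a parameter set records
which named overrides have been applied and re-application is a no-op.

- `btt`: activates the bridge-to-transplant pathway with the published
  monthly probabilities (device state → BTT listing 0.006; BTT →
  transplant 0.028). BTT/HT utilities and costs are not in the main text;
  their defaults are synthetic config fields (post-transplant utility
  0.74, transplant episode £60,000, immunosuppression £300/month, HT
  mortality multiplier 0.3).
- `intermacs1`, `intermacs23`, `intermacs45`: subgroup overrides scaling
  arm mortality and replacing baseline utilities, synthetic but directed —
  lower INTERMACS profile ⇒ higher mortality and lower utility in both
  arms, with profile 1 far worse than 4–5.

## Numerical choices and degenerate inputs

- Trace conservation is asserted at 1e-9 every run; transition rows at
  1e-12.
- Event probabilities summing above 1 in a row raise a validation error
  naming the row; probabilities, utilities and costs are range-checked on
  load with all failures reported together with dotted paths.
- Utilities are floored at 0 after decrements; the beta/gamma PSA families
  respect bounds by construction (beta variances are capped just inside
  the feasible `m(1−m)` limit).
- Calibration root finding uses tolerance 1e-10 on the two-year death gap;
  infeasible targets (including cost anchors below the fixed one-off
  spend, or solved utilities outside (0.3, 1]) abort with an explicit
  error rather than clamping.
- YAML serialisation keeps 15 significant digits so `load(serialize(x))`
  round-trips to numerical precision.
- Percentiles are order statistics (`type = 1`), making PSA summaries
  exactly reproducible functions of the draw set.

## Problem sizes used in the test suite

The suite runs the lifetime model (540 cycles) throughout; the
individual-level oracle uses 100,000 simulated patients over 24 cycles on
a four-state instance; the randomized invariant suite uses 100 generated
parameter sets (plus 10 small PSAs for CEAC monotonicity); the CEAC-shape
check uses 2,000 probabilistic draws. These sizes put Monte-Carlo error
well below the asserted tolerances while keeping the whole suite around a
minute on one core.

## Known limitations

- Cohort (expected-value) engine only; individual-level simulation exists
  solely as a test oracle, so the model cannot produce patient-level
  variance or history-dependent risks.
- Independence of PSA draws by default; structural uncertainty (e.g. the
  month-24 freeze vs. trend extrapolation) is explored through scenarios,
  not sampled.
- The synthetic defaults are anchored to four published totals and two
  death fractions; all other magnitudes are plausible but invented, so
  subgroup and scenario outputs are qualitative, not estimates.
- Background mortality uses a static sex mix rather than tracking
  differential survival by sex; at a 50/50 mix and these disease
  mortalities the error is negligible relative to parameter uncertainty.
- No value-of-information analysis.
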