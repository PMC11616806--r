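population:
  start_age: 65.0
  female_fraction: 0.5
  age_cap: 110.0
  cohort_size: 1000.0
discounting:
  annual_discount: 0.035
mortality:
  lvad_monthly:
  - 0.016599181407838
  - 0.014763318443303
  - 0.013333546928912
  - 0.01222003975389
  - 0.011352839494028
  - 0.010677463252568
  - 0.010151479706851
  - 0.009741843309564
  - 0.009422818162582
  - 0.009174361128293
  - 0.008980862595429
  - 0.008830165786511
  - 0.00871280299372
  - 0.008621400758791
  - 0.008550216626653
  - 0.008494778368803
  - 0.008451603010176
  - 0.008417978007069
  - 0.008391790828318
  - 0.008371396233
  - 0.008355512906196
  - 0.008343142958843
  - 0.008333509234159
  - 0.00832600648183
  mm_monthly:
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  - 0.090462749277924
  lvad_multiplier: 1.0
  mm_multiplier: 1.0
  event_multipliers:
    dt: 1.0
    nds: 1.5
    ds: 2.5
    rhf: 2.0
    ar: 1.5
    mm: 1.0
    btt: 1.0
    ht: 0.3
events:
  nds: 0.002531017326284
  ds: 0.002058185849455
  rhf: 0.003145706726704
  ar: 0.001908207789995
  mm_nds: 0.003605045793112
  mm_ds: 0.003796779369935
  btt: 0.0
  ht: 0.0
complications:
  gib:
    prob: 0.019446752686054
    cost: 3322.0
    decrement: 0.081455702194944
  device_failure:
    prob: 0.001123572540935
    cost: 6030.0
    decrement: 0.0676556752529
  driveline_infection:
    prob: 0.006748091386631
    cost: 3152.0
    decrement: 0.068492070999928
  pump_infection:
    prob: 0.00199539848417
    cost: 10023.0
    decrement: 0.119433426638134
  pump_exchange:
    prob: 0.001070052769152
    cost: 35549.0
    decrement: 0.193470523110591
  arrhythmia:
    prob: 0.006060712606413
    cost: 2478.0
    decrement: 0.03376665287884
  mm_readmission:
    prob: 0.098705446810927
    cost: 2772.0
    decrement: 0.0
costs:
  device: 109140.0
  implant_op: 12000.0
  icu_day: 1600.0
  icu_days: 7.0
  ward_day: 350.0
  ward_days: 14.0
  event_oneoff:
    nds: 3000.0
    ds: 12000.0
    rhf: 6000.0
    ar: 5000.0
    ht: 60000.0
  state_monthly:
    nds: 100.0
    ds: 1000.0
    rhf: 400.0
    ar: 200.0
  outpatient_lvad_monthly: 207.629955187471182
  outpatient_mm_monthly: 1686.226244551000491
  ht_monthly: 300.0
utilities:
  lvad_baseline: 0.697033755612641
  mm_baseline: 0.60031150335222
  ht: 0.74
  decrements:
    nds: 0.07
    ds: 0.25
    rhf: 0.15
    ar: 0.1
psa:
  entries:
  - path: utilities.lvad_baseline
    family: beta
    rel_se: 0.04
  - path: utilities.mm_baseline
    family: beta
    rel_se: 0.05
  - path: mortality.lvad_multiplier
    family: lognormal
    rel_se: 0.06
  - path: mortality.mm_multiplier
    family: lognormal
    rel_se: 0.06
  - path: costs.outpatient_lvad_monthly
    family: gamma
    rel_se: 0.12
  - path: costs.outpatient_mm_monthly
    family: gamma
    rel_se: 0.12
  - path: costs.device
    family: gamma
    rel_se: 0.07
  - path: costs.implant_op
    family: gamma
    rel_se: 0.1
  - path: events.nds
    family: beta
    rel_se: 0.2
  - path: events.ds
    family: beta
    rel_se: 0.2
  - path: events.rhf
    family: beta
    rel_se: 0.2
  - path: events.ar
    family: beta
    rel_se: 0.2
  - path: events.mm_nds
    family: beta
    rel_se: 0.2
  - path: events.mm_ds
    family: beta
    rel_se: 0.2
  - path: complications.gib.prob
    family: beta
    rel_se: 0.2
  - path: complications.driveline_infection.prob
    family: beta
    rel_se: 0.2
  - path: complications.arrhythmia.prob
    family: beta
    rel_se: 0.2
  - path: complications.mm_readmission.prob
    family: beta
    rel_se: 0.2
  - path: complications.gib.cost
    family: gamma
    rel_se: 0.15
  - path: complications.driveline_infection.cost
    family: gamma
    rel_se: 0.15
  - path: complications.arrhythmia.cost
    family: gamma
    rel_se: 0.15
  - path: complications.mm_readmission.cost
    family: gamma
    rel_se: 0.15
scenarios:
  btt:
    set:
      events.btt: 0.006
      events.ht: 0.028
  intermacs1:
    set:
      utilities.lvad_baseline: 0.55
      utilities.mm_baseline: 0.17
    scale:
      mortality.lvad_multiplier: 1.55
      mortality.mm_multiplier: 2.4
  intermacs23:
    set:
      utilities.lvad_baseline: 0.65
      utilities.mm_baseline: 0.39
    scale:
      mortality.lvad_multiplier: 1.3
  intermacs45:
    set:
      utilities.lvad_baseline: 0.72
      utilities.mm_baseline: 0.51
    scale:
      mortality.lvad_multiplier: 1.2
      mortality.mm_multiplier: 0.92

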