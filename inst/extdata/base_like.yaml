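schema_version: 1
arpi_abi_share: 0.5
ctdna_ppv:
  dist: beta
  mean: 0.85
  se: 0.03
ctdna_flag_fraction:
  dist: beta
  mean: 0.4
  se: 0.04
ctdna_cost_per_sample:
  dist: gamma
  mean: 350.0
  se: 35.0
ctdna_n_samples: 3
visit_cost_per_cycle:
  dist: gamma
  mean: 120.0
  se: 12.0
diagnostic_cost:
  dist: gamma
  mean: 250.0
  se: 25.0
bsc_cost_per_cycle:
  dist: gamma
  mean: 450.0
  se: 45.0
bsc_entry_rate_per_day: 2.0e-05
discount_rate_costs: 0.04
discount_rate_effects: 0.015
wtp: 80000.0
horizon_years: 5.0
cycle1_days: 28.0
cycle_days: 21.0
cohort_size: 1000.0
durable_hold: no
lines:
  abiraterone:
    pfs:
      form: exponential_median
      median: 16.5
      median_se: 1.65
    os:
      form: exponential_median
      median: 34.700000000000003
      median_se: 3.470000000000001
    drug_cost_per_cycle:
      dist: gamma
      mean: 700.0
      se: 70.0
    admin_cost_per_cycle: 0.0
    utility:
      dist: beta
      mean: 0.78
      se: 0.05
    ae_events:
    - prob:
        dist: beta
        mean: 0.1
        se: 0.01
      cost:
        dist: gamma
        mean: 2500.0
        se: 250.0
  enzalutamide:
    pfs:
      form: exponential_median
      median: 17.0
      median_se: 1.7
    os:
      form: exponential_median
      median: 35.0
      median_se: 3.5
    drug_cost_per_cycle:
      dist: gamma
      mean: 2450.0
      se: 245.0
    admin_cost_per_cycle: 0.0
    utility:
      dist: beta
      mean: 0.78
      se: 0.05
    ae_events:
    - prob:
        dist: beta
        mean: 0.1
        se: 0.01
      cost:
        dist: gamma
        mean: 2500.0
        se: 250.0
  arpi_durable_responder:
    pfs:
      form: exponential_median
      median: 36.75
      median_se: 3.675
    os:
      form: exponential_median
      median: 74.849999999999994
      median_se: 7.484999999999999
    drug_cost_per_cycle: 0.0
    admin_cost_per_cycle: 0.0
    utility:
      dist: beta
      mean: 0.78
      se: 0.05
    ae_events: []
  docetaxel:
    pfs:
      form: exponential_median
      median: 8.300000000000001
      median_se: 0.83
    os:
      form: exponential_median
      median: 24.300000000000001
      median_se: 2.43
    drug_cost_per_cycle:
      dist: gamma
      mean: 120.0
      se: 12.0
    admin_cost_per_cycle:
      dist: gamma
      mean: 350.0
      se: 35.0
    utility:
      dist: beta
      mean: 0.72
      se: 0.05
    ae_events:
    - prob:
        dist: beta
        mean: 0.35
        se: 0.035
      cost:
        dist: gamma
        mean: 4000.0
        se: 400.0
    max_cycles: 10.0
  cabazitaxel:
    pfs:
      form: exponential_median
      median: 5.5
      median_se: 0.55
    os:
      form: exponential_median
      median: 13.6
      median_se: 1.36
    drug_cost_per_cycle:
      dist: gamma
      mean: 3900.0
      se: 390.0
    admin_cost_per_cycle:
      dist: gamma
      mean: 350.0
      se: 35.0
    utility:
      dist: beta
      mean: 0.69
      se: 0.05
    ae_events:
    - prob:
        dist: beta
        mean: 0.3
        se: 0.03
      cost:
        dist: gamma
        mean: 4000.0
        se: 400.0
    max_cycles: 10.0
  cabazitaxel_proselica:
    pfs:
      form: exponential_median
      median: 3.5
      median_se: 0.35
    os:
      form: exponential_median
      median: 14.5
      median_se: 1.45
    drug_cost_per_cycle:
      dist: gamma
      mean: 3900.0
      se: 390.0
    admin_cost_per_cycle:
      dist: gamma
      mean: 350.0
      se: 35.0
    utility:
      dist: beta
      mean: 0.69
      se: 0.05
    ae_events:
    - prob:
        dist: beta
        mean: 0.3
        se: 0.03
      cost:
        dist: gamma
        mean: 4000.0
        se: 400.0
    max_cycles: 10.0
  bsc:
    os:
      form: exponential_median
      median: 7.0
      median_se: 0.7
    drug_cost_per_cycle: 0.0
    admin_cost_per_cycle: 0.0
    utility:
      dist: beta
      mean: 0.52
      se: 0.05
    ae_events: []
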