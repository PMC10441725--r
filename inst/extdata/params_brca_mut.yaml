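subgroup: brca_mut
settings:
  cycle_length_days: 21.0
  horizon_years: 15.0
  half_cycle_correction: yes
patient:
  body_weight: 70.0
  body_surface_area: 1.84
  serum_creatinine: 1.0
econ:
  utility_pfs: 0.84
  utility_pd: 0.79
  admin_cost_per_cycle: 124.0
  lab_cost_per_cycle: 4.0
  imaging_cost_per_cycle: 105.0
  brca_test_cost: 2901.0
  hrd_test_cost: 4682.0
  carboplatin_cost_per_cycle: 23.0
  paclitaxel_cost_per_cycle: 35.0
  second_line_duration_cycles: 6
  bsc_cost_per_cycle: 4143.0
  terminal_care_cost: 85904.0
  discount_rate_annual: 0.03
  wtp_per_qaly: 150000.0
  disutilities:
    lymphopenia: 0.09
    fatigue: 0.17
    neutropenia: 0.0
    anemia: 0.0
    hypertension: 0.0
arms:
  intervention:
    name: olaparib_bevacizumab
    pfs:
      family: weibull
      scale: 0.005312
      shape: 1.20865
    os:
      family: weibull
      scale: 0.0008312
      shape: 1.4656368
    olaparib_cost_per_cycle: 3657.0
    bevacizumab_cost_per_cycle: 7326.0
    olaparib_max_cycles: 35
    bevacizumab_max_cycles: 22
    ae_risks:
      fatigue: 0.05
      neutropenia: 0.06
      lymphopenia: 0.07
      anemia: 0.17
      hypertension: 0.19
    ae_management_cost: 291.0
    second_line_proportion: 0.484
  comparator:
    name: bevacizumab
    pfs:
      family: weibull
      scale: 0.022464
      shape: 1.082455
    os:
      family: weibull
      scale: 0.0016336
      shape: 1.4217268
    olaparib_cost_per_cycle: 0.0
    bevacizumab_cost_per_cycle: 7326.0
    olaparib_max_cycles: 0
    bevacizumab_max_cycles: 22
    ae_risks:
      hypertension: 0.3
    ae_management_cost: 76.0
    second_line_proportion: 0.61
psa:
- name: econ.utility_pfs
  family: beta
  mean: 0.84
  low: 0.672
  high: 1.008
- name: econ.utility_pd
  family: beta
  mean: 0.79
  low: 0.632
  high: 0.948
- name: econ.disutilities.lymphopenia
  family: beta
  mean: 0.09
  low: 0.072
  high: 0.108
- name: econ.disutilities.fatigue
  family: beta
  mean: 0.17
  low: 0.136
  high: 0.204
- name: intervention.ae_risks.fatigue
  family: beta
  mean: 0.05
  low: 0.04
  high: 0.06
- name: intervention.ae_risks.neutropenia
  family: beta
  mean: 0.06
  low: 0.048
  high: 0.072
- name: intervention.ae_risks.lymphopenia
  family: beta
  mean: 0.07
  low: 0.056
  high: 0.084
- name: intervention.ae_risks.anemia
  family: beta
  mean: 0.17
  low: 0.136
  high: 0.204
- name: intervention.ae_risks.hypertension
  family: beta
  mean: 0.19
  low: 0.152
  high: 0.228
- name: comparator.ae_risks.hypertension
  family: beta
  mean: 0.3
  low: 0.24
  high: 0.36
- name: intervention.second_line_proportion
  family: beta
  mean: 0.484
  low: 0.387
  high: 0.581
- name: comparator.second_line_proportion
  family: beta
  mean: 0.61
  low: 0.488
  high: 0.732
- name: patient.body_weight
  family: normal
  mean: 70.0
  low: 56.0
  high: 84.0
- name: patient.body_surface_area
  family: normal
  mean: 1.84
  low: 1.47
  high: 2.21
- name: econ.discount_rate_annual
  family: uniform
  mean: 0.03
  low: 0.0
  high: 0.05
- name: drugs.olaparib_cost_per_cycle
  family: gamma
  mean: 3657.0
  low: 2926.0
  high: 4388.0
- name: drugs.bevacizumab_cost_per_cycle
  family: gamma
  mean: 7326.0
  low: 5861.0
  high: 8791.0
- name: econ.carboplatin_cost_per_cycle
  family: gamma
  mean: 23.0
  low: 18.0
  high: 28.0
- name: econ.paclitaxel_cost_per_cycle
  family: gamma
  mean: 35.0
  low: 28.0
  high: 42.0
- name: intervention.ae_management_cost
  family: gamma
  mean: 291.0
  low: 233.0
  high: 349.0
- name: comparator.ae_management_cost
  family: gamma
  mean: 76.0
  low: 61.0
  high: 91.0
- name: econ.lab_cost_per_cycle
  family: gamma
  mean: 4.0
  low: 3.0
  high: 5.0
- name: econ.imaging_cost_per_cycle
  family: gamma
  mean: 105.0
  low: 84.0
  high: 126.0
- name: econ.admin_cost_per_cycle
  family: gamma
  mean: 124.0
  low: 99.0
  high: 149.0
- name: econ.brca_test_cost
  family: gamma
  mean: 2901.0
  low: 2321.0
  high: 3481.0
- name: econ.hrd_test_cost
  family: gamma
  mean: 4682.0
  low: 3746.0
  high: 5618.0
- name: econ.bsc_cost_per_cycle
  family: gamma
  mean: 4143.0
  low: 3314.0
  high: 4972.0
- name: econ.terminal_care_cost
  family: gamma
  mean: 85904.0
  low: 68723.0
  high: 103085.0
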