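params:
  egfr_mutation_freq:
    base: 0.5
    low: 0.08
    high: 0.7
    distribution: beta
  hr_pfs_gefitinib_egfr_pos:
    base: 0.17
    low: 0.07
    high: 0.42
    distribution: lognormal_from_ci
  p_secondline:
    base: 0.566
    low: 0.26
    high: 0.72
    distribution: beta
  p_sae_gefitinib:
    base: 0.07
    low: 0.0525
    high: 0.0875
    distribution: beta
  p_sae_control:
    base: 0.03
    low: 0.0225
    high: 0.0375
    distribution: beta
  p_sae_platinum:
    base: 0.8
    low: 0.6
    high: 1.0
    distribution: beta
  cost_genotyping:
    base: 507.9
    low: 381.0
    high: 634.9
    distribution: lognormal
  cost_gefitinib_250mg:
    base: 77.8
    low: 38.9
    high: 77.8
    distribution: lognormal
  cost_followup_visit:
    base: 55.6
    low: 41.7
    high: 69.4
    distribution: lognormal
  cost_secondline_cycle:
    base: 2352.7
    low: 1921.1
    high: 4383.3
    distribution: lognormal
  cost_endoflife:
    base: 3664.3
    low: 21.4
    high: 48750.199999999997
    distribution: lognormal
  cost_supportive_cycle:
    base: 337.5
    low: 158.7
    high: 793.7
    distribution: lognormal
  cost_sae_platinum_cycle:
    base: 507.4
    low: 189.7
    high: 825.0
    distribution: lognormal
  utility_pfs:
    base: 0.65
    low: 0.26
    high: 0.87
    distribution: beta
  utility_pd:
    base: 0.47
    low: 0.19
    high: 0.58
    distribution: beta
weibull:
  pfs_control:
    scale: 0.1559
    shape: 1.045
    time_unit: cycle
    adj_r2: 0.976
  os_supportive:
    scale: 0.04006
    shape: 1.156
    time_unit: week
    adj_r2: 0.9898
  os_secondline:
    scale: 0.03897
    shape: 1.509
    time_unit: week
    adj_r2: 0.981
settings:
  cycle_days: 21.0
  horizon_years: 10.0
  discount_annual: 0.03
  gpap: no
  gpap_paid_months: 6.0
  secondline_cycles: 4.0
  followup_early_interval_months: 4.0
  followup_late_interval_months: 12.0
  followup_early_years: 2.0
  followup_scope: alive
  hr_egfr_neg: 1.0
  half_cycle: no
  wtp:
    china: 16349.1
    shanghai: 38733.300000000003
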