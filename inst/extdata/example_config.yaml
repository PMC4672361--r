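# Example pipeline configuration. Every key is optional; anything omitted
# keeps the package default (see ?default_config). Concentrations are ng/L.
seed: 1

synthetic:
  n_villages_per_group: 20
  missingness_rate: 0.0333333333
  village_sd: 0.4
  sd_log: 0.7
  incidence:
    risk: {mean: 397.47, sd: 92.35}
    control: {mean: 134.89, sd: 50.33}
    mortality_risk: {mean: 313.44, sd: 73.83}
    mortality_control: {mean: 140.06, sd: 71.73}
    r: 0.78

exposure:
  ir_l_per_day: 2.39
  ef_days_per_year: 350
  ed_years: 70
  bw_kg: 62.1
  at_days: 25550
  sa_cm2: 16000
  kp_cm_per_h: 1.2
  et_h_per_day: 0.15
  sf_oral: 7.3
  aaf: 0.92

standards:
  china: {bap_ng_l: 10, total_ng_l: 2000, bapeq_ng_l: 10}
  us: {bap_ng_l: 200}
  egypt: {bap_ng_l: 700}

mc:
  n: 10000
  cv: {bw: 0.2, et: 0.2, ir: 0.2, sa: 0.2}
  ed_range: [0, 70]

stats:
  nd_policy_sums: zero
  nd_policy_gm: half_dl

# To analyse your own monitoring data instead of a synthetic campaign:
# io:
#   samples: path/to/samples.csv
#   villages: path/to/villages.csv
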