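schema_version: 1
wtp: 30828.0
cycles:
  cycle_length_days: 21.0
  horizon_years: 10.0
discount:
  annual_rate: 0.03
patient:
  height: 1.64
  weight: 65.0
  bsa: 1.72
strategies:
- name: gefitinib
  arm: gefitinib
  dfs_median: 30.8
  os_median: 75.5
  shape: 1.0
  followup_cost: 55.6
  supportive_cost: 337.5
  pd_entry_cost: 1877.25
  ae_cost: 507.4
  ae_incidence: 0.12
  ae_disutility: 0.0731
  dfs_utility: 0.8
  pd_utility: 0.7
- name: chemotherapy
  arm: chemotherapy
  dfs_median: 19.8
  os_median: 62.8
  shape: 1.0
  followup_cost: 55.6
  supportive_cost: 337.5
  pd_entry_cost: 1877.25
  ae_cost: 507.4
  ae_incidence: 0.48
  ae_disutility: 0.0731
  dfs_utility: 0.76
  pd_utility: 0.7
unit_costs:
  gefitinib_tablet: 23.33
  vinorelbine_vial: 8.16
  cisplatin_vial: 2.8
psa:
  'n': 1000
  seed: 42
  se_convention: range/(2*1.96)
metadata:
  currency: USD
  usd_cny_exchange_rate: 6.8409
  source: published adjuvant-trial parameter tables
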