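arm_a:
  arm_name: zilver_ptx
  r12: 0.089655172413793102
  r24: 0.20100000000000001
  m12_perc: 0.95999999999999996
  m12_open: 0.040000000000000001
  m24_perc: 0.97099999999999997
  m24_open: 0.029000000000000001
  a12: 0.0
  a24: 0.0070000000000000001
  h12: 1.2480769504889653
  h24: 2.7782999734724534
  stent_price: 0.0
arm_b:
  arm_name: eluvia
  r12: 0.045296167247386762
  r24: 0.127
  m12_perc: 0.96699999999999997
  m12_open: 0.033000000000000002
  m24_perc: 0.95699999999999996
  m24_open: 0.042999999999999997
  a12: 0.0034843205574912892
  a24: 0.014999999999999999
  h12: 0.53980581823774731
  h24: 2.2359999666681629
  stent_price: 0.0
costs:
  c_percutaneous: 5495.0
  c_open: 16411.0
  c_amputation: 35354.0
  c_bed_day: 2003.0
  c_primary: 5495.0
population:
  type: cohort_schedule
  'N':
  - 5674.0
  - 6060.0
  - 6474.0
  - 6915.0
  - 7386.0
  - 7890.0
  year_labels:
  - 2019
  - 2020
  - 2021
  - 2022
  - 2023
  - 2024
n_years: 6
second_cycle_mode: cumulative_recount
state_shares:
  NSW & ACT: 0.33112205747667023
  VIC: 0.25297655882571352
  SA: 0.068986856110299755
  WA: 0.10307185821431224
  NT: 0.0098764820911408698
  QLD: 0.19725735785539247
  TAS: 0.02091635931582465
scenario_ranges:
  evp_eligibility:
  - 0.69999999999999996
  - 0.98999999999999999
  des_use_rate:
  - 0.10000000000000001
  - 0.40000000000000002
  stent_price_multiplier:
  - 0.90000000000000002
  - 1.1000000000000001
  bed_day_multiplier:
  - 0.90000000000000002
  - 1.1000000000000001
  cohort_factor:
  - 0.0
  - Inf
enforce_scenario_bounds: yes

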