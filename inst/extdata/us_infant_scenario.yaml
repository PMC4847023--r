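schema_version: 1
simulation:
  n_iterations: 1000000.0
  seed: 20160325
  percentiles:
  - 25.0
  - 50.0
  - 75.0
toxicology:
  mrl_acute_mg_per_kg_day: 0.005
  mrl_chronic_mg_per_kg_day: 0.0003
  csf_per_mg_per_kg_day: 1.5
  mcl_water_mg_per_L: 0.01
  exposure_duration_days: 620.0
  averaging_time_days: 25550.0
concentrations:
  water_mg_per_L:
    family: uniform
    low: 0.0
    high: 0.01
  formula_mg_per_g_dry:
    family: normal
    mean: 7.48e-06
    sd: 6.12e-07
    truncate_at_zero: yes
  rice_cereal_mg_per_g:
    family: triangular
    a: 2.3e-05
    b: 9.1e-05
    c: 0.000283
  other_solid_mg_per_g:
    family: normal
    mean: 4.6e-06
    sd: 5.6e-06
    truncate_at_zero: yes
age_bands:
- label: 4-5
  months:
  - 4
  - 5
  body_weight_kg:
    family: normal
    mean: 6.95
    sd: 0.85
  water_L_per_day:
    family: triangular
    a: 0.0
    b: 0.148
    c: 0.924
  rice_cereal_g_per_day:
    family: normal
    mean: 14.300000000000001
    sd: 16.100000000000001
    truncate_at_zero: yes
  formula_g_dry_per_serving:
    family: normal
    mean: 21.5
    sd: 9.699999999999999
    truncate_at_zero: yes
  formula_servings_per_day:
  - 4
  - 5
  fruit_g_per_serving:
    family: normal
    mean: 58.700000000000003
    sd: 77.400000000000006
    truncate_at_zero: yes
  fruit_servings_per_day:
  - 1
  - 2
  vegetable_g_per_serving:
    family: normal
    mean: 61.899999999999999
    sd: 81.400000000000006
    truncate_at_zero: yes
  vegetable_servings_per_day:
  - 1
  - 2
- label: 6-8
  months:
  - 6
  - 7
  - 8
  body_weight_kg:
    family: normal
    mean: 7.95
    sd: 1.08
  water_L_per_day:
    family: triangular
    a: 0.0
    b: 0.218
    c: 0.885
  rice_cereal_g_per_day:
    family: normal
    mean: 20.699999999999999
    sd: 17.100000000000001
    truncate_at_zero: yes
  formula_g_dry_per_serving:
    family: normal
    mean: 22.800000000000001
    sd: 11.4
    truncate_at_zero: yes
  formula_servings_per_day:
  - 3
  - 4
  fruit_g_per_serving:
    family: normal
    mean: 76.599999999999994
    sd: 47.700000000000003
    truncate_at_zero: yes
  fruit_servings_per_day:
  - 1
  - 2
  vegetable_g_per_serving:
    family: normal
    mean: 94.5
    sd: 69.400000000000006
    truncate_at_zero: yes
  vegetable_servings_per_day:
  - 1
  - 2
  meat_g_per_serving:
    family: normal
    mean: 25.5
    sd: 120.700000000000003
    truncate_at_zero: yes
  meat_servings_per_day:
  - 1
  - 2
- label: 9-11
  months:
  - 9
  - 10
  - 11
  body_weight_kg:
    family: normal
    mean: 9.029999999999999
    sd: 1.05
  water_L_per_day:
    family: triangular
    a: 0.0
    b: 0.218
    c: 0.885
  rice_cereal_g_per_day:
    family: normal
    mean: 23.899999999999999
    sd: 21.699999999999999
    truncate_at_zero: yes
  formula_g_dry_per_serving:
    family: normal
    mean: 24.100000000000001
    sd: 10.1
    truncate_at_zero: yes
  formula_servings_per_day:
  - 3
  - 4
  fruit_g_per_serving:
    family: normal
    mean: 94.5
    sd: 72.599999999999994
    truncate_at_zero: yes
  fruit_servings_per_day:
  - 1
  - 2
  vegetable_g_per_serving:
    family: normal
    mean: 91.299999999999997
    sd: 85.5
    truncate_at_zero: yes
  vegetable_servings_per_day:
  - 2
  - 3
  meat_g_per_serving:
    family: normal
    mean: 22.699999999999999
    sd: 37.200000000000003
    truncate_at_zero: yes
  meat_servings_per_day:
  - 1
  - 2
- label: 12-14
  months:
  - 12
  - 13
  - 14
  body_weight_kg:
    family: normal
    mean: 9.93
    sd: 1.08
  water_L_per_day:
    family: triangular
    a: 0.0
    b: 0.188
    c: 0.624
  rice_cereal_g_per_day:
    family: normal
    mean: 44.200000000000003
    sd: 70.900000000000006
    truncate_at_zero: yes
  formula_g_dry_per_serving:
    family: normal
    mean: 24.5
    sd: 22.399999999999999
    truncate_at_zero: yes
  formula_servings_per_day:
  - 3
  - 4
  fruit_g_per_serving:
    family: normal
    mean: 104.299999999999997
    sd: 100.5
    truncate_at_zero: yes
  fruit_servings_per_day:
  - 1
  - 2
  vegetable_g_per_serving:
    family: normal
    mean: 104.299999999999997
    sd: 100.5
    truncate_at_zero: yes
  vegetable_servings_per_day:
  - 2
  - 3
  meat_g_per_serving:
    family: normal
    mean: 34.0
    sd: 32.799999999999997
    truncate_at_zero: yes
  meat_servings_per_day:
  - 1
  - 2
- label: 15-18
  months:
  - 15
  - 16
  - 17
  - 18
  body_weight_kg:
    family: normal
    mean: 10.9
    sd: 1.5
  water_L_per_day:
    family: triangular
    a: 0.0
    b: 0.188
    c: 0.624
  rice_cereal_g_per_day:
    family: normal
    mean: 44.200000000000003
    sd: 70.900000000000006
    truncate_at_zero: yes
  formula_g_dry_per_serving:
    family: normal
    mean: 25.399999999999999
    sd: 52.399999999999999
    truncate_at_zero: yes
  formula_servings_per_day:
  - 3
  - 4
  fruit_g_per_serving:
    family: normal
    mean: 130.400000000000006
    sd: 138.199999999999989
    truncate_at_zero: yes
  fruit_servings_per_day:
  - 1
  - 2
  vegetable_g_per_serving:
    family: normal
    mean: 104.299999999999997
    sd: 138.199999999999989
    truncate_at_zero: yes
  vegetable_servings_per_day:
  - 2
  - 3
  meat_g_per_serving:
    family: normal
    mean: 36.899999999999999
    sd: 40.100000000000001
    truncate_at_zero: yes
  meat_servings_per_day:
  - 1
  - 2
- label: 19-24
  months:
  - 19
  - 20
  - 21
  - 22
  - 23
  - 24
  body_weight_kg:
    family: normal
    mean: 11.85
    sd: 1.38
  water_L_per_day:
    family: triangular
    a: 0.0
    b: 0.188
    c: 0.624
  rice_cereal_g_per_day:
    family: normal
    mean: 51.5
    sd: 65.799999999999997
    truncate_at_zero: yes
  formula_g_dry_per_serving:
    family: normal
    mean: 20.199999999999999
    sd: 75.400000000000006
    truncate_at_zero: yes
  formula_servings_per_day:
  - 3
  - 4
  fruit_g_per_serving:
    family: normal
    mean: 156.5
    sd: 134.0
    truncate_at_zero: yes
  fruit_servings_per_day:
  - 1
  - 2
  vegetable_g_per_serving:
    family: normal
    mean: 104.299999999999997
    sd: 93.299999999999997
    truncate_at_zero: yes
  vegetable_servings_per_day:
  - 2
  - 3
  meat_g_per_serving:
    family: normal
    mean: 36.899999999999999
    sd: 35.5
    truncate_at_zero: yes
  meat_servings_per_day:
  - 1
  - 2
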