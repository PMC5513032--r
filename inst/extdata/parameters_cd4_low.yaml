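start_age_years: 38.0
prev_disease: 0.33
split_diseased:
  LSIL: 0.0
  HSIL: 0.952
  local: 0.02
  regional: 0.024
  distant: 0.004
split_nondiseased:
  normal: 0.832
  LSIL: 0.169
ltfu_2visit: 0.32
ltfu_3visit: 0.48
smr: 2.54
cancer_mortality_monthly:
  local: 0.004
  regional: 0.021
  distant: 0.063
progression_monthly:
  normal_lsil: 0.001
  lsil_hsil: 0.003
  hsil_local: 0.002
  local_regional: 0.003
  regional_distant: 0.003
regression_monthly:
  lsil_normal: 0.003
  hsil_lsil: 0.0
  hsil_normal: 0.0
treatment_effectiveness: 0.9
cure_monthly: 0.15
side_effect_monthly: 0.01
p_side_effect_major: 0.16
test_performance:
  Pap:
    sensitivity: 0.76
    specificity: 0.93
  VIA:
    sensitivity: 0.76
    specificity: 0.62
  HPV:
    sensitivity: 0.92
    specificity: 0.46
  VIA+HPV:
    sensitivity: 0.58
    specificity: 0.84
  VIA+Pap:
    sensitivity: 0.51
    specificity: 0.99
  HPV+Pap:
    sensitivity: 0.63
    specificity: 0.99
unit_costs:
  societal:
    screening:
      Pap: 39.0
      VIA: 18.0
      HPV: 32.0
    treatment:
      cryotherapy: 48.0
      colposcopy: 160.0
      LEEP: 86.0
    side_effects:
      major: 974.0
      minor: 203.0
    cancer_care:
      local: 1135.0
      regional: 6447.0
      distant: 5107.0
      palliative_monthly: 196.0
  clinic:
    screening:
      Pap: 24.0
      VIA: 10.0
      HPV: 18.0
    treatment:
      cryotherapy: 12.0
      colposcopy: 109.0
      LEEP: 20.0
    side_effects:
      major: 847.0
      minor: 178.0
    cancer_care:
      local: 112.0
      regional: 149.0
      distant: 144.0
      palliative_monthly: 145.0
discount_monthly: 0.0025
p_cryo_given_treatment: 0.8
visit_indirect_cost:
  single_visit: 0.43
  multi_visit: 2.88
symptomatic_detection:
  local: no
  regional: yes
  distant: yes
ranges: []
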