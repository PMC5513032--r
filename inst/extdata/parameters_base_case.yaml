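start_age_years: 38.0
prev_disease: 0.22
split_diseased:
  LSIL: 0.0
  HSIL: 0.952
  local: 0.02
  regional: 0.024
  distant: 0.004
split_nondiseased:
  normal: 0.902
  LSIL: 0.098
ltfu_2visit: 0.32
ltfu_3visit: 0.48
smr: 1.77
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
    sensitivity: 0.74
    specificity: 0.98
  VIA:
    sensitivity: 0.61
    specificity: 0.63
  HPV:
    sensitivity: 0.81
    specificity: 0.55
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
ranges:
  start_age_years:
    low: 30.0
    high: 46.0
  prev_disease:
    low: 0.18
    high: 0.27
  split_diseased.HSIL:
    low: 0.762
    high: 1.0
  split_diseased.local:
    low: 0.016
    high: 0.024
  split_diseased.regional:
    low: 0.019
    high: 0.029
  split_diseased.distant:
    low: 0.003
    high: 0.005
  split_nondiseased.LSIL:
    low: 0.078
    high: 0.118
  split_nondiseased.normal:
    low: 0.722
    high: 1.0
  ltfu_2visit:
    low: 0.0
    high: 0.4
  ltfu_3visit:
    low: 0.3
    high: 0.6
  smr:
    low: 1.42
    high: 2.12
  cancer_mortality_monthly.local:
    low: 0.003
    high: 0.005
  cancer_mortality_monthly.regional:
    low: 0.017
    high: 0.025
  cancer_mortality_monthly.distant:
    low: 0.051
    high: 0.076
  progression_monthly.normal_lsil:
    low: 0.0
    high: 0.002
  progression_monthly.lsil_hsil:
    low: 0.002
    high: 0.004
  progression_monthly.hsil_local:
    low: 0.001
    high: 0.003
  progression_monthly.local_regional:
    low: 0.002
    high: 0.004
  progression_monthly.regional_distant:
    low: 0.002
    high: 0.004
  regression_monthly.lsil_normal:
    low: 0.002
    high: 0.004
  regression_monthly.hsil_lsil:
    low: 0.0
    high: 0.001
  regression_monthly.hsil_normal:
    low: 0.0
    high: 0.001
  treatment_effectiveness:
    low: 0.7
    high: 1.0
  cure_monthly:
    low: 0.12
    high: 0.18
  side_effect_monthly:
    low: 0.0
    high: 0.02
  p_side_effect_major:
    low: 0.13
    high: 0.2
  sensitivity.Pap:
    low: 0.59
    high: 0.89
  sensitivity.VIA:
    low: 0.49
    high: 0.73
  sensitivity.HPV:
    low: 0.65
    high: 0.97
  sensitivity.VIA+HPV:
    low: 0.46
    high: 0.7
  sensitivity.VIA+Pap:
    low: 0.41
    high: 0.61
  sensitivity.HPV+Pap:
    low: 0.5
    high: 0.76
  specificity.Pap:
    low: 0.78
    high: 1.0
  specificity.VIA:
    low: 0.5
    high: 0.76
  specificity.HPV:
    low: 0.44
    high: 0.66
  specificity.VIA+HPV:
    low: 0.67
    high: 1.0
  specificity.VIA+Pap:
    low: 0.79
    high: 1.0
  specificity.HPV+Pap:
    low: 0.79
    high: 1.0
  cost.screening.Pap:
    low: 31.0
    high: 47.0
  cost.screening.VIA:
    low: 14.0
    high: 22.0
  cost.screening.HPV:
    low: 26.0
    high: 38.0
  cost.treatment.cryotherapy:
    low: 38.0
    high: 58.0
  cost.treatment.colposcopy:
    low: 128.0
    high: 192.0
  cost.treatment.LEEP:
    low: 69.0
    high: 103.0
  cost.side_effects.major:
    low: 779.0
    high: 1169.0
  cost.side_effects.minor:
    low: 162.0
    high: 244.0
  cost.cancer_care.local:
    low: 908.0
    high: 1362.0
  cost.cancer_care.regional:
    low: 5158.0
    high: 7736.0
  cost.cancer_care.distant:
    low: 4086.0
    high: 6128.0
  cost.cancer_care.palliative_monthly:
    low: 157.0
    high: 235.0
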