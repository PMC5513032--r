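# Shared fixtures, all built in code.

base_params <- function() default_parameters()

base_life_table <- function() synthetic_life_table()

# Disease-free cohort: no prevalent disease, no incidence.
zero_disease_params <- function(p = default_parameters()) {
  p$prev_disease <- 0
  p$split_nondiseased <- c(normal = 1, LSIL = 0)
  p$progression_monthly[] <- 0
  p$regression_monthly[] <- 0
  p$cancer_mortality_monthly[] <- 0
  p
}

# Strip every cost and side-effect exposure so only life-years accrue.
zero_cost_params <- function(p = default_parameters()) {
  for (persp in c("societal", "clinic"))
    p$unit_costs[[persp]] <- lapply(p$unit_costs[[persp]],
                                    function(v) { v[] <- 0; v })
  p$side_effect_monthly <- 0
  p$visit_indirect_cost[] <- 0
  p
}

# Constant annual mortality q at every age until closure at age_max. The
# default closure is far enough out that horizon truncation is < 1e-12 of the
# infinite-horizon annuity for q >= 0.02.
constant_mortality_table <- function(q, age_min = 38, age_max = 600) {
  synthetic_life_table(makeham_a = -log(1 - q), makeham_b = 0,
                       makeham_c = 2, age_min = age_min, age_max = age_max)
}

# Closed-form discounted life expectancy for a disease-free cohort under
# constant annual mortality q, monthly discount d (infinite-horizon annuity).
annuity_le <- function(q, d) {
  s <- (1 - q)^(1 / 12)
  v <- 1 / (1 + d)
  1 / (12 * (1 - s * v))
}
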