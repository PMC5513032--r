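test_that("the strategy roster has the published visit structure", {
  ss <- strategies()
  expect_named(ss, c("cryo_all", "VIA", "Pap", "HPV",
                     "VIA+HPV", "VIA+Pap", "HPV+Pap"))
  expect_equal(ss$cryo_all$n_visits, 1L)
  expect_length(ss$cryo_all$tests, 0)
  expect_equal(ss$VIA$n_visits, 1L)
  expect_equal(ss$Pap$n_visits, 2L)
  expect_equal(ss$HPV$n_visits, 2L)
  expect_equal(ss$`VIA+Pap`$n_visits, 3L)
  expect_error(strategy("colposcopy"), "unknown strategy")
})

test_that("classification fires sensitivity at CIN2+ and 1-spec below", {
  p <- base_params()
  expect_equal(classify("VIA", "HSIL", p), 0.61)
  expect_equal(classify("Pap", "Normal", p), 1 - 0.98)
  expect_equal(classify("HPV", "LSIL", p), 1 - 0.55)
  for (s in c("LocalCancer", "RegionalCancer", "DistantCancer"))
    expect_equal(classify("HPV", s, p), 0.81)
  expect_error(classify("CT-scan", "HSIL", p), "unknown test")
})

test_that("cascade completion reflects visits and loss to follow-up", {
  p <- base_params()
  expect_equal(cascade_completion_probability(strategy("HPV"), p), 0.68)
  expect_equal(cascade_completion_probability(strategy("VIA+Pap"), p), 0.52)
  expect_equal(cascade_completion_probability(strategy("VIA"), p), 1)
  expect_equal(cascade_completion_probability(strategy("cryo_all"), p), 1)
  expect_equal(cascade_completion_probability(
    strategy("HPV", single_visit_override = TRUE), p), 1)
})

test_that("expected side-effect cost matches its closed form", {
  p <- base_params()
  expect_equal(expected_side_effect_cost(p, "societal"),
               0.01 * (0.16 * 974 + 0.84 * 203))
  expect_equal(expected_side_effect_cost(p, "clinic"),
               0.01 * (0.16 * 847 + 0.84 * 178))
  expect_equal(expected_side_effect_cost(
    set_parameter(p, "side_effect_monthly", 0), "societal"), 0)
})

test_that("cascade outcomes price screening, treatment mix and workup", {
  p <- base_params()

  cc <- build_cascade(strategy("cryo_all"), p, "clinic")
  expect_true(all(cc$p_treat == 1))
  expect_true(all(cc$p_cancer_workup == 0))
  expect_equal(unname(cc$cost), rep(12 + 0.01 * (0.16 * 847 + 0.84 * 178), 9))

  cv <- build_cascade(strategy("VIA"), p, "societal")
  sse <- 0.01 * (0.16 * 974 + 0.84 * 203)
  mix <- 0.8 * 48 + 0.2 * 86
  expect_equal(unname(cv$p_treat[["Normal"]]), 0.37)
  expect_equal(unname(cv$cost[["Normal"]]), 18 + 0.37 * (mix + sse))
  expect_equal(unname(cv$cost[["HSIL"]]), 18 + 0.61 * (mix + sse))
  # cancer completers: colposcopy + stage cost, no cryo/LEEP
  expect_equal(unname(cv$p_cancer_workup[["RegionalCancer"]]), 0.61)
  expect_equal(unname(cv$cost[["RegionalCancer"]]), 18 + 0.61 * (160 + 6447))

  cp <- build_cascade(strategy("Pap"), p, "societal")
  expect_equal(unname(cp$p_treat[["HSIL"]]), 0.74 * 0.68)

  # pair strategies charge both tests and use their joint performance
  cb <- build_cascade(strategy("VIA+HPV"), p, "societal")
  expect_equal(unname(cb$p_treat[["HSIL"]]), 0.58 * 0.52)
  expect_equal(unname(cb$cost[["LSIL"]]) -
                 unname(cb$p_treat[["LSIL"]]) * (mix + sse), 18 + 32)

  expect_error(build_cascade(strategy("VIA"), p, "insurer"), "perspective")
})

test_that("perfect specificity eliminates false-positive treatment cost", {
  p <- base_params()
  for (nm in names(p$test_performance))
    p <- set_parameter(p, paste0("specificity.", nm), 1)
  for (st in c("VIA", "Pap", "HPV", "VIA+HPV", "VIA+Pap", "HPV+Pap")) {
    cs <- build_cascade(strategy(st), p, "societal")
    uc <- sum(p$unit_costs$societal$screening[strategy(st)$tests])
    expect_equal(unname(cs$p_treat[["Normal"]]), 0)
    expect_equal(unname(cs$p_treat[["LSIL"]]), 0)
    expect_equal(unname(cs$cost[["Normal"]]), uc)
    expect_equal(unname(cs$cost[["LSIL"]]), uc)
  }
})

test_that("treatment probability is monotone in sensitivity and completion", {
  p <- base_params()
  p_treat_at_sens <- vapply(c(0.49, 0.61, 0.73, 0.9), function(sens) {
    ps <- set_parameter(p, "sensitivity.VIA", sens)
    build_cascade(strategy("VIA"), ps, "societal")$p_treat[["HSIL"]]
  }, numeric(1))
  expect_true(all(diff(p_treat_at_sens) > 0))
  p_treat_at_ltfu <- vapply(c(0, 0.2, 0.32, 0.4), function(l) {
    pl <- set_parameter(p, "ltfu_2visit", l)
    build_cascade(strategy("HPV"), pl, "societal")$p_treat[["HSIL"]]
  }, numeric(1))
  expect_true(all(diff(p_treat_at_ltfu) < 0))
})

test_that("single-visit override removes one visit's indirect societal cost", {
  p <- base_params()
  two <- build_cascade(strategy("HPV"), p, "societal")
  one <- build_cascade(strategy("HPV", single_visit_override = TRUE),
                       p, "societal")
  expect_equal(unname(two$cost[["LocalCancer"]] - one$cost[["LocalCancer"]] -
    (two$p_cancer_workup[["LocalCancer"]] - one$p_cancer_workup[["LocalCancer"]]) *
      (160 + 1135)), 2.88 - 0.43)
  # clinic screening cost is unchanged by the override
  two_c <- build_cascade(strategy("HPV"), p, "clinic")
  one_c <- build_cascade(strategy("HPV", single_visit_override = TRUE),
                         p, "clinic")
  expect_equal(unname(one_c$cost[["Normal"]] - two_c$cost[["Normal"]]),
               unname((one_c$p_treat[["Normal"]] - two_c$p_treat[["Normal"]]) *
                        (0.8 * 12 + 0.2 * 20 +
                           expected_side_effect_cost(p, "clinic"))))
})
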