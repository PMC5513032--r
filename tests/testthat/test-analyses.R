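test_that("scenario table reproduces the qualitative strategy rankings", {
  p <- base_params()
  lt <- base_life_table()
  tab <- base_case_and_scenarios(p, lt)
  expect_equal(nrow(tab), 21)

  for (sc in c("base", "cd4_low", "cd4_high")) {
    sub <- tab[tab$scenario == sc, ]
    # preventative cryotherapy cheapest under both perspectives, highest LE
    expect_equal(sub$strategy[which.min(sub$cost_societal)], "cryo_all")
    expect_equal(sub$strategy[which.min(sub$cost_clinic)], "cryo_all")
    expect_equal(sub$strategy[which.max(sub$le_discounted)], "cryo_all")
    # pairs cost more and yield no more LE than their most effective member
    singles <- sub[sub$strategy %in% c("VIA", "Pap", "HPV"), ]
    pairs <- sub[sub$strategy %in% c("VIA+HPV", "VIA+Pap", "HPV+Pap"), ]
    expect_gt(min(pairs$cost_societal), max(singles$cost_societal))
    expect_lte(max(pairs$le_discounted), max(singles$le_discounted))
    # VIA is the cheapest screening strategy
    expect_lt(sub$cost_societal[sub$strategy == "VIA"],
              min(sub$cost_societal[sub$strategy %in% c("Pap", "HPV")]))
  }

  # CD4 stratification shifts LE in the published directions for every strategy
  wide <- reshape(tab[, c("scenario", "strategy", "le_discounted")],
                  idvar = "strategy", timevar = "scenario", direction = "wide")
  expect_true(all(wide$le_discounted.cd4_high > wide$le_discounted.base))
  expect_true(all(wide$le_discounted.cd4_low < wide$le_discounted.base))
})

test_that("tornado entries span both strategies' cost response and sort by swing", {
  p <- base_params()
  lt <- base_life_table()
  tor <- tornado("VIA_minus_cryo", p, lt)
  expect_setequal(tor$parameter, names(p$ranges))
  expect_true(all(diff(tor$swing) <= 1e-12))
  base_delta <- attr(tor, "base_delta")
  expect_equal(base_delta,
               run_strategy("VIA", p, lt)$lifetime_cost -
                 run_strategy("cryo_all", p, lt)$lifetime_cost)
  # VIA remains more expensive than preventative cryotherapy in every one-way run
  expect_true(all(tor$delta_low > 0))
  expect_true(all(tor$delta_high > 0))
  # a parameter VIA does not use leaves the incremental cost at base
  row <- tor[tor$parameter == "cost.screening.Pap", ]
  expect_equal(row$delta_low, base_delta, tolerance = 1e-9)
  expect_equal(row$delta_high, base_delta, tolerance = 1e-9)
  # the VIA screening cost moves the delta dollar-for-dollar
  row <- tor[tor$parameter == "cost.screening.VIA", ]
  expect_equal(row$delta_high - row$delta_low, 22 - 14, tolerance = 1e-9)

  # degenerate ranges collapse every bar to the base delta
  p2 <- p
  p2$ranges <- lapply(names(p2$ranges), function(nm) {
    b <- get_parameter(p2, nm); c(low = b, high = b)
  })
  names(p2$ranges) <- names(p$ranges)
  tor2 <- tornado("HPV_minus_VIA", p2, lt)
  expect_equal(tor2$delta_low, tor2$delta_high)
})

test_that("single-visit conversion lowers Pap and HPV costs, never LE", {
  p <- base_params()
  lt <- base_life_table()
  sv <- single_visit_scenario(p, lt)
  for (nm in c("Pap", "HPV")) {
    two <- sv[sv$strategy == nm & sv$visits == "2-visit", ]
    one <- sv[sv$strategy == nm & sv$visits == "1-visit", ]
    expect_lt(one$cost, two$cost)
    expect_gte(one$le_discounted, two$le_discounted)
  }
  # VIA is already single-visit: the override is a no-op
  via <- run_strategy(strategy("VIA"), p, lt)
  via1 <- run_strategy(strategy("VIA", single_visit_override = TRUE), p, lt)
  expect_equal(via1$lifetime_cost, via$lifetime_cost)
  expect_equal(via1$le_discounted, via$le_discounted)
})

test_that("the LTFU threshold agrees with a 101-point grid search", {
  p <- base_params()
  lt <- base_life_table()
  root <- ltfu_threshold(p, lt)
  expect_true(is.finite(root))
  expect_true(root > 0 && root < p$ltfu_2visit)

  cost_via <- run_strategy("VIA", p, lt)$lifetime_cost
  grid <- seq(0, p$ltfu_2visit, length.out = 101)
  diffs <- vapply(grid, function(l)
    run_strategy("HPV", set_parameter(p, "ltfu_2visit", l), lt)$lifetime_cost -
      cost_via, numeric(1))
  # lower LTFU means more completed treatment, fewer cancers, lower lifetime
  # cost for HPV; the sign of the difference flips once across the bracket
  expect_true(all(diff(sign(diffs)) >= 0))
  expect_lt(abs(root - grid[which.min(abs(diffs))]), diff(grid)[1] + 1e-12)

  # at the root the two strategies' costs agree to the bisection tolerance
  at_root <- run_strategy("HPV", set_parameter(p, "ltfu_2visit", root),
                          lt)$lifetime_cost
  expect_lt(abs(at_root - cost_via), 0.01 + 1e-9)

  # limiting case: HPV priced and performing exactly like VIA reaches parity
  # only at completion parity, LTFU -> 0
  pe <- set_parameter(p, "sensitivity.HPV", p$test_performance$VIA$sensitivity)
  pe <- set_parameter(pe, "specificity.HPV", p$test_performance$VIA$specificity)
  pe$unit_costs$societal$screening[["HPV"]] <-
    pe$unit_costs$societal$screening[["VIA"]]
  pe$unit_costs$clinic$screening[["HPV"]] <-
    pe$unit_costs$clinic$screening[["VIA"]]
  expect_lt(ltfu_threshold(pe, lt), 0.01)

  # a degenerate bracket cannot contain a sign change
  expect_message(
    res <- ltfu_threshold(set_parameter(p, "ltfu_2visit", 0), lt),
    "no threshold")
  expect_true(is.na(res))
})
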