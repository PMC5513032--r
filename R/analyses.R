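#' @title Analytic products
#' @description
#' The comparisons the model exists to make: lifetime cost and life
#' expectancy per strategy for the base case and the two CD4 scenarios,
#' one-way (tornado) sensitivity analyses of the two incremental cost
#' comparisons (VIA vs preventative cryotherapy, HPV vs VIA), the
#' single-visit scenario for Pap and HPV, and the loss-to-follow-up level at
#' which a two-visit HPV cascade costs the same as single-visit VIA.
#' @name analyses
NULL

#' Base case and CD4 scenario results
#'
#' Runs all seven strategies under both cost perspectives for the base case
#' and the CD4 <= 200 and CD4 > 500 scenarios.
#'
#' @param params Base-case `cervcost_params`.
#' @param lt A `cervcost_life_table`.
#' @return A data frame with columns `scenario`, `strategy`,
#'   `cost_societal`, `cost_clinic`, `le_discounted`, `le_undiscounted`;
#'   within each scenario rows are ordered by societal cost ascending.
#' @export
base_case_and_scenarios <- function(params, lt) {
  out <- lapply(c("base", "cd4_low", "cd4_high"), function(sc) {
    tab <- run_all(apply_scenario(params, sc), lt)
    cbind(scenario = sc, tab)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

.tornado_arms <- list(
  VIA_minus_cryo = c("VIA", "cryo_all"),
  HPV_minus_VIA = c("HPV", "VIA")
)

#' One-way (tornado) sensitivity analysis of an incremental cost
#'
#' For every ranged parameter, re-runs both strategies of the comparison at
#' the parameter's min and max (all else at base) and records the incremental
#' lifetime cost at each end. Entries are sorted by the width of the swing,
#' `|delta_high - delta_low|`, descending.
#'
#' @param comparison `"VIA_minus_cryo"` (VIA cost minus preventative
#'   cryotherapy cost) or `"HPV_minus_VIA"`.
#' @param params Base-case `cervcost_params`.
#' @param lt A `cervcost_life_table` (must cover the start-age range, ages
#'   30-46, for the start-age entry).
#' @param perspective Cost perspective, default `"societal"`.
#' @return A data frame (`parameter`, `low`, `high`, `delta_low`,
#'   `delta_high`, `swing`) with the base-case incremental cost in attribute
#'   `"base_delta"`.
#' @export
tornado <- function(comparison = c("VIA_minus_cryo", "HPV_minus_VIA"),
                    params, lt, perspective = "societal") {
  comparison <- match.arg(comparison)
  arms <- .tornado_arms[[comparison]]
  delta <- function(p) {
    run_strategy(arms[1], p, lt, perspective)$lifetime_cost -
      run_strategy(arms[2], p, lt, perspective)$lifetime_cost
  }
  entries <- enumerate_oneway(params)
  rows <- lapply(entries, function(e) {
    data.frame(parameter = e$name, low = e$low, high = e$high,
               delta_low = delta(e$low_set), delta_high = delta(e$high_set),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$swing <- abs(out$delta_high - out$delta_low)
  out <- out[order(-out$swing), , drop = FALSE]
  attr(out, "base_delta") <- delta(params)
  attr(out, "comparison") <- comparison
  out
}

#' Single-visit scenario for the two-visit tests
#'
#' Re-runs Pap and HPV with the cascade compressed to one visit (completion
#' probability 1, one visit's indirect cost), alongside their two-visit base
#' results.
#'
#' @param params Base-case `cervcost_params`.
#' @param lt A `cervcost_life_table`.
#' @param perspective Cost perspective, default `"societal"`.
#' @return A data frame with columns `strategy`, `visits`, `cost`,
#'   `le_discounted`.
#' @export
single_visit_scenario <- function(params, lt, perspective = "societal") {
  rows <- lapply(c("Pap", "HPV"), function(nm) {
    base <- run_strategy(strategy(nm), params, lt, perspective)
    sv <- run_strategy(strategy(nm, single_visit_override = TRUE),
                       params, lt, perspective)
    rbind(
      data.frame(strategy = nm, visits = "2-visit", cost = base$lifetime_cost,
                 le_discounted = base$le_discounted),
      data.frame(strategy = nm, visits = "1-visit", cost = sv$lifetime_cost,
                 le_discounted = sv$le_discounted))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Loss-to-follow-up threshold at HPV/VIA cost parity
#'
#' Finds the two-visit LTFU probability at which the HPV strategy's lifetime
#' cost equals single-visit VIA's, by bisection on `ltfu_2visit` over
#' `[0, base]` to within `tol` dollars. Only HPV's cascade depends on
#' `ltfu_2visit` in this comparison (VIA completes in one visit), so only
#' that parameter is varied.
#'
#' @param params Base-case `cervcost_params`.
#' @param lt A `cervcost_life_table`.
#' @param perspective Cost perspective, default `"societal"`.
#' @param tol Absolute cost tolerance at the root, in dollars.
#' @return The threshold LTFU probability, or `NA` (with a message) when the
#'   cost difference does not change sign on the bracket.
#' @export
ltfu_threshold <- function(params, lt, perspective = "societal", tol = 0.01) {
  cost_via <- run_strategy("VIA", params, lt, perspective)$lifetime_cost
  f <- function(l) {
    p <- set_parameter(params, "ltfu_2visit", l)
    run_strategy("HPV", p, lt, perspective)$lifetime_cost - cost_via
  }
  lo <- 0; hi <- params$ltfu_2visit
  f_lo <- f(lo); f_hi <- f(hi)
  if (sign(f_lo) == sign(f_hi)) {
    message("no threshold in range: cost(HPV) - cost(VIA) keeps sign on [0, ",
            hi, "]")
    return(NA_real_)
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (abs(f_mid) < tol) return(mid)
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  (lo + hi) / 2
}
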