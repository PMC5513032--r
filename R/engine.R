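#' @title Deterministic cohort engine
#' @description
#' Iterates the probability mass vector over the health states in monthly
#' cycles from the start age to the life-table horizon, accruing discounted
#' costs and life-years. Month 0 applies the initial state distribution and
#' the screening cascade (costs and state reassignments); every later month
#' applies the age-specific transition matrix, charges treated-state costs
#' (monthly palliative care for treated regional/distant disease pre-cure,
#' monthly side-effect risk in any treated cancer state), and resolves
#' symptomatic detection of undiagnosed invasive cancer. Costs and benefits
#' are discounted at 0.25% per month; life-years accrue 1/12 per live
#' person-month at the start of each survived month (no half-cycle
#' correction).
#' @name cohort_engine
NULL

.stage_of <- c(LocalCancer = "local", RegionalCancer = "regional",
               DistantCancer = "distant")
.treated_of <- c(LocalCancer = "LocalTreated", RegionalCancer = "RegionalTreated",
                 DistantCancer = "DistantTreated")

# Move undiagnosed cancer mass in symptomatic stages to the treated states,
# charging the stage cost at discount factor v. Returns list(x, cost_added).
.detect_symptomatic <- function(x, params, uc, v) {
  added <- 0
  det <- params$symptomatic_detection
  for (s in names(.stage_of)) {
    stage <- .stage_of[[s]]
    if (isTRUE(det[[stage]]) && x[[s]] > 0) {
      added <- added + x[[s]] * uc$cancer_care[[stage]] * v
      x[[.treated_of[[s]]]] <- x[[.treated_of[[s]]]] + x[[s]]
      x[[s]] <- 0
    }
  }
  list(x = x, cost = added)
}

# Apply month-0 cascade reassignments to a state vector given a cascade
# outcome: treated HSIL regresses to Normal with the treatment effectiveness;
# cancer completers move to their treated state.
.apply_cascade_states <- function(x, casc, params) {
  moved <- x[["HSIL"]] * casc$p_treat[["HSIL"]] * params$treatment_effectiveness
  x[["HSIL"]] <- x[["HSIL"]] - moved
  x[["Normal"]] <- x[["Normal"]] + moved
  for (s in names(.treated_of)) {
    m <- x[[s]] * casc$p_cancer_workup[[s]]
    x[[s]] <- x[[s]] - m
    x[[.treated_of[[s]]]] <- x[[.treated_of[[s]]]] + m
  }
  x
}

# Transition matrices for every completed age the run can visit.
.matrix_cache <- function(params, lt, age0, age_last) {
  ages <- seq.int(age0, age_last)
  stats::setNames(lapply(ages, function(a)
    build_transition_matrix(params, lt, a)), ages)
}

#' Run one strategy through the cohort model
#'
#' @param strat A `cervcost_strategy` (or strategy name).
#' @param params A `cervcost_params` object.
#' @param lt A `cervcost_life_table` covering
#'   `[start_age_years, horizon age]`.
#' @param perspective `"societal"` or `"clinic"`.
#' @param trace If `TRUE`, keep the per-cycle state distribution.
#' @return An object of class `cervcost_result`: `lifetime_cost` (discounted,
#'   2014 USD), `le_discounted` and `le_undiscounted` (years from screening),
#'   `cycles`, and optionally `trace` (cycles x 11 matrix).
#' @export
run_strategy <- function(strat, params, lt, perspective = "societal",
                         trace = FALSE) {
  if (is.character(strat)) strat <- strategy(strat)
  uc <- params$unit_costs[[perspective]]
  if (is.null(uc)) stop("unknown perspective: ", perspective, call. = FALSE)
  age0 <- params$start_age_years
  max_age <- max(lt$age)
  if (age0 < min(lt$age) || age0 >= max_age)
    stop("life table does not cover the start age", call. = FALSE)
  T_max <- (max_age - age0) * 12
  d <- params$discount_monthly
  pall <- uc$cancer_care[["palliative_monthly"]]
  sse <- expected_side_effect_cost(params, perspective)

  x <- initial_state_distribution(params)
  casc <- build_cascade(strat, params, perspective)
  cost <- sum(x[.live_states] * casc$cost)
  x <- .apply_cascade_states(x, casc, params)
  det0 <- .detect_symptomatic(x, params, uc, v = 1)
  x <- det0$x
  cost <- cost + det0$cost

  mats <- .matrix_cache(params, lt, floor(age0), max_age - 1L)
  le_d <- 0; le_u <- 0
  tr <- if (trace) list(x) else NULL
  t <- 0L
  live_idx <- 1:9
  repeat {
    live <- sum(x[live_idx])
    if (live < 1e-9 || t >= T_max) break
    v <- (1 + d)^(-t)
    le_d <- le_d + live / 12 * v
    le_u <- le_u + live / 12
    M <- mats[[as.character(floor(age0 + t / 12))]]
    x <- drop(x %*% M)
    v1 <- (1 + d)^(-(t + 1L))
    # treated-state costs on the occupancy entering month t+1 (pre-detection,
    # so a detection month carries the stage cost only)
    occ_pall <- x[["RegionalTreated"]] + x[["DistantTreated"]]
    occ_sse <- x[["LocalTreated"]] + occ_pall
    cost <- cost + (occ_pall * pall + occ_sse * sse) * v1
    det <- .detect_symptomatic(x, params, uc, v1)
    x <- det$x
    cost <- cost + det$cost
    if (trace) tr[[length(tr) + 1L]] <- x
    t <- t + 1L
  }

  out <- list(strategy = strat$name,
              perspective = perspective,
              lifetime_cost = cost,
              le_discounted = le_d,
              le_undiscounted = le_u,
              cycles = t)
  if (trace) out$trace <- do.call(rbind, tr)
  class(out) <- "cervcost_result"
  out
}

#' @export
print.cervcost_result <- function(x, ...) {
  cat(sprintf("<cervcost_result> %s (%s)\n", x$strategy, x$perspective))
  cat(sprintf("  lifetime cost: $%.2f\n", x$lifetime_cost))
  cat(sprintf("  life expectancy: %.3f y discounted, %.3f y undiscounted\n",
              x$le_discounted, x$le_undiscounted))
  invisible(x)
}

#' Run a set of strategies under both perspectives
#'
#' @param params A `cervcost_params` object.
#' @param lt A `cervcost_life_table`.
#' @param strats List of strategies (default all seven).
#' @param perspectives Character vector of perspectives.
#' @return A data frame with one row per strategy (`strategy`,
#'   `cost_<perspective>` per perspective, `le_discounted`,
#'   `le_undiscounted`), ordered by societal cost ascending.
#' @export
run_all <- function(params, lt, strats = strategies(),
                    perspectives = c("societal", "clinic")) {
  rows <- lapply(strats, function(st) {
    res <- lapply(perspectives, function(pp) run_strategy(st, params, lt, pp))
    row <- data.frame(strategy = st$name, stringsAsFactors = FALSE)
    for (i in seq_along(perspectives))
      row[[paste0("cost_", perspectives[i])]] <- res[[i]]$lifetime_cost
    row$le_discounted <- res[[1]]$le_discounted
    row$le_undiscounted <- res[[1]]$le_undiscounted
    row
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  key <- if ("cost_societal" %in% names(out)) "cost_societal"
         else names(out)[startsWith(names(out), "cost_")][1]
  out[order(out[[key]]), , drop = FALSE]
}
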