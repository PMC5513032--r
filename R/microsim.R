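#' @title Individual-level microsimulation oracle
#' @description
#' Samples individual trajectories through the identical cascade and
#' transition logic as the deterministic cohort engine, as an independent
#' validation oracle: with a large sample the mean discounted cost and life
#' expectancy must agree with [run_strategy()] to within Monte Carlo error.
#' Where the cohort engine charges an expectation (the cryotherapy/LEEP mix,
#' side-effect events and severity), the microsimulation samples the actual
#' event, so agreement checks the full event structure and not only the
#' transition matrix.
#' @name microsimulation
NULL

# Sample next states for a vector of current states given the cumulative
# transition matrix (rows = states, cols = cumulative probabilities).
.sample_next <- function(cumM, state) {
  cp <- cumM[state, , drop = FALSE]
  u <- stats::runif(length(state))
  as.integer(rowSums(cp < u) + 1L)
}

#' Microsimulate one strategy
#'
#' @inheritParams run_strategy
#' @param n_individuals Number of sampled women (`>= 1`).
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return A list of class `cervcost_microsim`: `mean_cost`, `se_cost`,
#'   `le_discounted`, `se_le_discounted`, `le_undiscounted`,
#'   `se_le_undiscounted`, `n`, `seed`.
#' @export
microsimulate <- function(strat, params, lt, perspective = "societal",
                          n_individuals = 10000L, seed = 1L) {
  if (is.character(strat)) strat <- strategy(strat)
  stopifnot(n_individuals >= 1)
  set.seed(seed)
  uc <- params$unit_costs[[perspective]]
  n <- as.integer(n_individuals)
  age0 <- params$start_age_years
  max_age <- max(lt$age)
  T_max <- (max_age - age0) * 12
  d <- params$discount_monthly
  eff <- params$treatment_effectiveness
  sse_p <- params$side_effect_monthly
  sse_major <- params$p_side_effect_major
  c_major <- uc$side_effects[["major"]]
  c_minor <- uc$side_effects[["minor"]]
  pall <- uc$cancer_care[["palliative_monthly"]]
  det <- params$symptomatic_detection
  stage_cost <- uc$cancer_care

  S <- health_states()
  i_normal <- 1L; i_hsil <- 3L
  i_cancer <- 4:6; i_treated <- 7:9
  stage_name <- c("local", "regional", "distant")

  x0 <- initial_state_distribution(params)
  state <- sample.int(6L, n, replace = TRUE, prob = x0[1:6])
  cost <- numeric(n); le_d <- numeric(n); le_u <- numeric(n)

  draw_sse_cost <- function(k) {
    ev <- stats::runif(k) < sse_p
    maj <- stats::runif(k) < sse_major
    ifelse(ev, ifelse(maj, c_major, c_minor), 0)
  }
  draw_treat_cost <- function(k) {
    cryo <- stats::runif(k) < params$p_cryo_given_treatment
    ifelse(cryo, uc$treatment[["cryotherapy"]], uc$treatment[["LEEP"]])
  }

  # month-0 cascade
  if (strat$name == "cryo_all") {
    cost <- cost + uc$treatment[["cryotherapy"]] + draw_sse_cost(n)
    hs <- state == i_hsil
    cured <- hs & (stats::runif(n) < eff)
    state[cured] <- i_normal
  } else {
    comp <- cascade_completion_probability(strat, params)
    test <- if (length(strat$tests) == 2L)
      paste(strat$tests, collapse = "+") else strat$tests
    screen_cost <- sum(uc$screening[strat$tests])
    if (strat$single_visit_override && strat$n_visits > 1L &&
        perspective == "societal")
      screen_cost <- max(0, screen_cost -
        (params$visit_indirect_cost[["multi_visit"]] -
         params$visit_indirect_cost[["single_visit"]]))
    cost <- cost + screen_cost
    p_pos <- vapply(S[1:6], function(s) classify(test, s, params), numeric(1))
    pos <- stats::runif(n) < p_pos[state]
    completer <- stats::runif(n) < comp
    act <- pos & completer
    lesion_treated <- act & state <= 3L
    k <- sum(lesion_treated)
    if (k) {
      cost[lesion_treated] <- cost[lesion_treated] +
        draw_treat_cost(k) + draw_sse_cost(k)
      hs <- lesion_treated & state == i_hsil
      cured <- hs & (stats::runif(n) < eff)
      state[cured] <- i_normal
    }
    workup <- act & state >= 4L & state <= 6L
    if (any(workup)) {
      cost[workup] <- cost[workup] + uc$treatment[["colposcopy"]] +
        stage_cost[stage_name[state[workup] - 3L]]
      state[workup] <- state[workup] + 3L
    }
  }
  # month-0 symptomatic detection of remaining undiagnosed cancer
  for (j in 1:3) {
    if (isTRUE(det[[stage_name[j]]])) {
      hit <- state == i_cancer[j]
      if (any(hit)) {
        cost[hit] <- cost[hit] + stage_cost[[stage_name[j]]]
        state[hit] <- i_treated[j]
      }
    }
  }

  cum_mats <- lapply(.matrix_cache(params, lt, floor(age0), max_age - 1L),
                     function(M) t(apply(M, 1L, cumsum)))
  t <- 0L
  repeat {
    alive <- which(state <= 9L)
    if (!length(alive) || t >= T_max) break
    v <- (1 + d)^(-t)
    le_d[alive] <- le_d[alive] + v / 12
    le_u[alive] <- le_u[alive] + 1 / 12
    cumM <- cum_mats[[as.character(floor(age0 + t / 12))]]
    state[alive] <- .sample_next(cumM, state[alive])
    v1 <- (1 + d)^(-(t + 1L))
    # treated-state costs, pre-detection
    in_pall <- which(state %in% 8:9)
    if (length(in_pall)) cost[in_pall] <- cost[in_pall] + pall * v1
    in_tr <- which(state %in% 7:9)
    if (length(in_tr)) cost[in_tr] <- cost[in_tr] +
        draw_sse_cost(length(in_tr)) * v1
    for (j in 1:3) {
      if (isTRUE(det[[stage_name[j]]])) {
        hit <- which(state == i_cancer[j])
        if (length(hit)) {
          cost[hit] <- cost[hit] + stage_cost[[stage_name[j]]] * v1
          state[hit] <- i_treated[j]
        }
      }
    }
    t <- t + 1L
  }

  out <- list(
    strategy = strat$name, perspective = perspective,
    mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
    le_discounted = mean(le_d),
    se_le_discounted = stats::sd(le_d) / sqrt(n),
    le_undiscounted = mean(le_u),
    se_le_undiscounted = stats::sd(le_u) / sqrt(n),
    n = n, seed = seed)
  class(out) <- "cervcost_microsim"
  out
}

#' @export
print.cervcost_microsim <- function(x, ...) {
  cat(sprintf("<cervcost_microsim> %s (%s), n = %d\n",
              x$strategy, x$perspective, x$n))
  cat(sprintf("  cost: $%.2f (SE %.2f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  LE:   %.3f y (SE %.4f)\n",
              x$le_discounted, x$se_le_discounted))
  invisible(x)
}
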