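#' @title Screen-and-treat cascade
#' @description
#' Seven once-in-a-lifetime strategies: preventative cryotherapy for all
#' women without screening (`cryo_all`), single tests (VIA, Pap, HPV) and
#' test pairs (VIA+HPV, VIA+Pap, HPV+Pap). VIA is same-day screen-and-treat
#' (1 visit); Pap and HPV require a results/treatment visit (2 visits); pairs
#' add a confirmatory screen (3 visits). Multi-visit cascades lose women to
#' follow-up before the treatment visit: lost women accrue all screening
#' costs but no treatment, no treatment benefit and no side effects. Women
#' treated for lesions (true HSIL and false positives) receive cryotherapy
#' with probability 0.8 and LEEP otherwise; screen-positive completers in an
#' invasive-cancer state receive colposcopy (staging gateway) plus the
#' stage-specific cancer-care package and enter the corresponding treated
#' state.
#' @name screening_cascade
NULL

.strategy_defs <- list(
  cryo_all  = list(n_visits = 1L, tests = character(0)),
  "VIA"     = list(n_visits = 1L, tests = "VIA"),
  "Pap"     = list(n_visits = 2L, tests = "Pap"),
  "HPV"     = list(n_visits = 2L, tests = "HPV"),
  "VIA+HPV" = list(n_visits = 3L, tests = c("VIA", "HPV")),
  "VIA+Pap" = list(n_visits = 3L, tests = c("VIA", "Pap")),
  "HPV+Pap" = list(n_visits = 3L, tests = c("HPV", "Pap"))
)

#' Construct a screening strategy
#'
#' @param name One of `cryo_all`, `VIA`, `Pap`, `HPV`, `VIA+HPV`, `VIA+Pap`,
#'   `HPV+Pap`.
#' @param single_visit_override If `TRUE`, the cascade is compressed to a
#'   single visit: completion probability 1 and one visit's indirect
#'   (societal) cost per screen.
#' @return An object of class `cervcost_strategy`.
#' @export
strategy <- function(name, single_visit_override = FALSE) {
  if (!name %in% names(.strategy_defs))
    stop("unknown strategy: ", name, call. = FALSE)
  d <- .strategy_defs[[name]]
  structure(list(name = name, n_visits = d$n_visits, tests = d$tests,
                 single_visit_override = single_visit_override),
            class = "cervcost_strategy")
}

#' All seven strategies
#'
#' @return Named list of `cervcost_strategy` objects in canonical order.
#' @export
strategies <- function() {
  stats::setNames(lapply(names(.strategy_defs), strategy),
                  names(.strategy_defs))
}

#' Probability that a test reads positive in a true state
#'
#' True positivity is defined at the CIN2+ threshold: HSIL and all invasive
#' cancer states are true positives (the test fires with its sensitivity);
#' Normal and LSIL are true negatives (the test fires with one minus its
#' specificity). Pair strategies use the pair's own published joint
#' sensitivity/specificity under its test name.
#'
#' @param test_name A key of `params$test_performance`.
#' @param true_state A live state name from [health_states()].
#' @param params A `cervcost_params` object.
#' @return Probability of a positive screen.
#' @export
classify <- function(test_name, true_state, params) {
  tp <- params$test_performance[[test_name]]
  if (is.null(tp)) stop("unknown test: ", test_name, call. = FALSE)
  if (true_state %in% .test_positive_states) tp$sensitivity
  else 1 - tp$specificity
}

#' Probability of completing the cascade through treatment
#'
#' 1-visit strategies (and any strategy under the single-visit override)
#' complete with probability 1; 2-visit strategies with `1 - ltfu_2visit`;
#' 3-visit strategies with `1 - ltfu_3visit`.
#'
#' @param strat A `cervcost_strategy`.
#' @param params A `cervcost_params` object.
#' @return Completion probability.
#' @export
cascade_completion_probability <- function(strat, params) {
  if (strat$single_visit_override || strat$n_visits == 1L) return(1)
  if (strat$n_visits == 2L) return(1 - params$ltfu_2visit)
  1 - params$ltfu_3visit
}

#' Expected side-effect cost for one month of exposure
#'
#' `side_effect_monthly * (p_major * cost_major + (1 - p_major) * cost_minor)`.
#'
#' @param params A `cervcost_params` object.
#' @param perspective `"societal"` or `"clinic"`.
#' @return Expected cost in 2014 USD.
#' @export
expected_side_effect_cost <- function(params, perspective) {
  se <- params$unit_costs[[perspective]]$side_effects
  params$side_effect_monthly *
    (params$p_side_effect_major * se[["major"]] +
     (1 - params$p_side_effect_major) * se[["minor"]])
}

#' Build the month-0 cascade outcome for a strategy
#'
#' For each true state, the probability of lesion treatment
#' (`p_treat = P(screen positive) * completion` for Normal/LSIL/HSIL), the
#' probability of cancer staging and treatment initiation
#' (`p_cancer_workup` for the invasive states), and the expected month-0
#' cascade cost per woman in that state: screening unit costs for every
#' screened woman (both tests for pairs), the 80/20 cryotherapy/LEEP mix plus
#' one month of side-effect risk for lesion-treated women, and colposcopy
#' plus the stage-specific cancer-care cost for cancer completers. The
#' `cryo_all` arm screens no one: every live woman accrues the cryotherapy
#' cost and one month of side-effect risk, HSIL is treated (effectiveness
#' applies), and prevalent cancers are left to symptomatic detection.
#'
#' @param strat A `cervcost_strategy`.
#' @param params A `cervcost_params` object.
#' @param perspective `"societal"` or `"clinic"`.
#' @return A list of class `cervcost_cascade` with named vectors over the
#'   nine live states: `p_treat`, `p_cancer_workup`, `cost`.
#' @export
build_cascade <- function(strat, params, perspective) {
  if (!perspective %in% .cost_perspectives)
    stop("unknown perspective: ", perspective, call. = FALSE)
  uc <- params$unit_costs[[perspective]]
  live <- .live_states
  p_treat <- stats::setNames(numeric(9), live)
  p_workup <- stats::setNames(numeric(9), live)
  cost <- stats::setNames(numeric(9), live)

  sse <- expected_side_effect_cost(params, perspective)
  mix <- params$p_cryo_given_treatment * uc$treatment[["cryotherapy"]] +
    (1 - params$p_cryo_given_treatment) * uc$treatment[["LEEP"]]

  if (strat$name == "cryo_all") {
    p_treat[] <- 1
    cost[] <- uc$treatment[["cryotherapy"]] + sse
    out <- list(strategy = strat$name, perspective = perspective,
                p_treat = p_treat, p_cancer_workup = p_workup, cost = cost)
    class(out) <- "cervcost_cascade"
    return(out)
  }

  comp <- cascade_completion_probability(strat, params)
  test <- if (length(strat$tests) == 2L)
    paste(strat$tests, collapse = "+") else strat$tests
  screen_cost <- sum(uc$screening[strat$tests])
  if (strat$single_visit_override && strat$n_visits > 1L &&
      perspective == "societal")
    screen_cost <- max(0, screen_cost -
      (params$visit_indirect_cost[["multi_visit"]] -
       params$visit_indirect_cost[["single_visit"]]))

  for (s in .true_states) {
    p_pos <- classify(test, s, params)
    cost[s] <- screen_cost
    if (s %in% c("Normal", "LSIL", "HSIL")) {
      p_treat[s] <- p_pos * comp
      cost[s] <- cost[s] + p_treat[s] * (mix + sse)
    } else {
      p_workup[s] <- p_pos * comp
      stage <- c(LocalCancer = "local", RegionalCancer = "regional",
                 DistantCancer = "distant")[[s]]
      cost[s] <- cost[s] + p_workup[s] *
        (uc$treatment[["colposcopy"]] + uc$cancer_care[[stage]])
    }
  }
  out <- list(strategy = strat$name, perspective = perspective,
              p_treat = p_treat, p_cancer_workup = p_workup, cost = cost)
  class(out) <- "cervcost_cascade"
  out
}
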