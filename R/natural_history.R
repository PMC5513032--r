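#' @title Natural history of cervical disease
#' @description
#' The Markov state space tracks the grade of squamous intraepithelial lesion
#' (SIL framework) and the stage of invasive cancer, with parallel "treated"
#' cancer states and two absorbing death states: Normal, LSIL, HSIL,
#' LocalCancer, RegionalCancer, DistantCancer, LocalTreated, RegionalTreated,
#' DistantTreated, DeadCancer, DeadOther. Successfully treated lesions return
#' to Normal (progression parameters are population aggregates with no
#' history dependence, so Normal is the re-entry state; cancer recurrence is
#' not modeled).
#' @name natural_history
NULL

#' Markov health states
#'
#' @return Character vector of the 11 state names, in model order.
#' @export
health_states <- function() {
  c("Normal", "LSIL", "HSIL",
    "LocalCancer", "RegionalCancer", "DistantCancer",
    "LocalTreated", "RegionalTreated", "DistantTreated",
    "DeadCancer", "DeadOther")
}

.S <- stats::setNames(seq_len(11), health_states())
.live_states <- health_states()[1:9]
.true_states <- health_states()[1:6]
.test_positive_states <- c("HSIL", "LocalCancer", "RegionalCancer", "DistantCancer")

#' Initial state distribution at screening
#'
#' Mass over the 11 states at model entry: a fraction `prev_disease` of the
#' cohort carries HSIL or invasive cancer (split per `split_diseased`), the
#' remainder is Normal or LSIL (split per `split_nondiseased`). Split vectors
#' are treated as weights and normalized here, so printed shares that sum to
#' 1.001 (rounding) or single-component sensitivity excursions remain usable.
#'
#' @param params A `cervcost_params` object.
#' @return Named numeric vector over [health_states()] summing to 1.
#' @export
initial_state_distribution <- function(params) {
  sd <- params$split_diseased / sum(params$split_diseased)
  sn <- params$split_nondiseased / sum(params$split_nondiseased)
  prev <- params$prev_disease
  x <- stats::setNames(numeric(11), health_states())
  x["Normal"] <- (1 - prev) * sn[["normal"]]
  x["LSIL"] <- (1 - prev) * sn[["LSIL"]] + prev * sd[["LSIL"]]
  x["HSIL"] <- prev * sd[["HSIL"]]
  x["LocalCancer"] <- prev * sd[["local"]]
  x["RegionalCancer"] <- prev * sd[["regional"]]
  x["DistantCancer"] <- prev * sd[["distant"]]
  x
}

# Fill one live-state row: background death first, then conditional on
# surviving it the monthly event probabilities apply directly. `events` is a
# named vector of destination probabilities (pre-conditioning); residual mass
# stays in `state`.
.fill_row <- function(M, state, q_m, events) {
  if (sum(events) > 1 + 1e-12)
    stop("model construction error: monthly event probabilities exceed 1 in ",
         "row ", state, call. = FALSE)
  M[state, ] <- 0
  M[state, "DeadOther"] <- q_m
  surv <- 1 - q_m
  for (dest in names(events))
    M[state, dest] <- M[state, dest] + surv * events[[dest]]
  M[state, state] <- M[state, state] + surv * (1 - sum(events))
  M
}

#' Monthly transition matrix at an age
#'
#' Row-stochastic 11x11 matrix for one monthly cycle. Background mortality
#' (life table at the completed age, SMR on the hazard scale) is applied
#' first; conditional on surviving it, the monthly progression, regression,
#' cancer-mortality and cure probabilities apply directly. Treated cancer
#' states use cancer mortality and progression scaled by
#' `1 - treatment_effectiveness` and add the monthly cure probability to
#' Normal. Dead states are absorbing.
#'
#' @param params A `cervcost_params` object.
#' @param lt A `cervcost_life_table` covering the age.
#' @param age_years Age in years during the cycle.
#' @return An 11x11 row-stochastic matrix with dimnames [health_states()].
#' @export
build_transition_matrix <- function(params, lt, age_years) {
  q_m <- monthly_background_mortality(lt, age_years, params$smr)
  pr <- params$progression_monthly
  rg <- params$regression_monthly
  cm <- params$cancer_mortality_monthly
  fail <- 1 - params$treatment_effectiveness
  cure <- params$cure_monthly

  s <- health_states()
  M <- matrix(0, 11, 11, dimnames = list(s, s))
  diag(M) <- 1  # dead rows stay identity

  M <- .fill_row(M, "Normal", q_m, c(LSIL = pr[["normal_lsil"]]))
  M <- .fill_row(M, "LSIL", q_m,
                 c(HSIL = pr[["lsil_hsil"]], Normal = rg[["lsil_normal"]]))
  M <- .fill_row(M, "HSIL", q_m,
                 c(LocalCancer = pr[["hsil_local"]],
                   LSIL = rg[["hsil_lsil"]], Normal = rg[["hsil_normal"]]))
  M <- .fill_row(M, "LocalCancer", q_m,
                 c(DeadCancer = cm[["local"]],
                   RegionalCancer = pr[["local_regional"]]))
  M <- .fill_row(M, "RegionalCancer", q_m,
                 c(DeadCancer = cm[["regional"]],
                   DistantCancer = pr[["regional_distant"]]))
  M <- .fill_row(M, "DistantCancer", q_m, c(DeadCancer = cm[["distant"]]))
  M <- .fill_row(M, "LocalTreated", q_m,
                 c(DeadCancer = fail * cm[["local"]],
                   RegionalTreated = fail * pr[["local_regional"]],
                   Normal = cure))
  M <- .fill_row(M, "RegionalTreated", q_m,
                 c(DeadCancer = fail * cm[["regional"]],
                   DistantTreated = fail * pr[["regional_distant"]],
                   Normal = cure))
  M <- .fill_row(M, "DistantTreated", q_m,
                 c(DeadCancer = fail * cm[["distant"]], Normal = cure))
  M
}
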