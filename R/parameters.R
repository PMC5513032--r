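#' @title Model parameter set
#' @description
#' The full parameter set of the decision model: cohort start age, initial
#' prevalence and its split over lesion/cancer grades, loss-to-follow-up (LTFU)
#' probabilities for multi-visit cascades, the standardized mortality ratio
#' (SMR) for treated HIV-infected women, monthly progression / regression /
#' cancer-mortality probabilities, lesion-treatment effectiveness and monthly
#' cure probability for treated cancer, side-effect probabilities, screening
#' test performance (sensitivity/specificity) for six tests, unit costs (2014
#' USD) under societal and clinic perspectives, the monthly discount rate, and
#' one-way sensitivity ranges per parameter.
#'
#' Objects of class `cervcost_params` are plain lists; create them with
#' [default_parameters()] or [load_parameters()], modify single entries with
#' [set_parameter()], and re-validate with [validate_parameters()].
#' @name parameters
NULL

.live_tests <- c("Pap", "VIA", "HPV", "VIA+HPV", "VIA+Pap", "HPV+Pap")
.cost_perspectives <- c("societal", "clinic")

#' Base-case parameter set
#'
#' Returns the base-case parameter set (women with CD4 200-500 cells/mL),
#' including the one-way sensitivity ranges. All probabilities are monthly
#' unless named otherwise; costs are 2014 USD.
#'
#' @return A validated object of class `cervcost_params`.
#' @export
default_parameters <- function() {
  p <- list(
    start_age_years = 38,
    prev_disease = 0.22,
    split_diseased = c(LSIL = 0, HSIL = 0.952, local = 0.020,
                       regional = 0.024, distant = 0.004),
    split_nondiseased = c(normal = 0.902, LSIL = 0.098),
    ltfu_2visit = 0.32,
    ltfu_3visit = 0.48,
    smr = 1.77,
    cancer_mortality_monthly = c(local = 0.004, regional = 0.021, distant = 0.063),
    progression_monthly = c(normal_lsil = 0.001, lsil_hsil = 0.003,
                            hsil_local = 0.002, local_regional = 0.003,
                            regional_distant = 0.003),
    regression_monthly = c(lsil_normal = 0.003, hsil_lsil = 0.000,
                           hsil_normal = 0.000),
    treatment_effectiveness = 0.9,
    cure_monthly = 0.15,
    side_effect_monthly = 0.01,
    p_side_effect_major = 0.16,
    test_performance = list(
      "Pap"     = list(sensitivity = 0.74, specificity = 0.98),
      "VIA"     = list(sensitivity = 0.61, specificity = 0.63),
      "HPV"     = list(sensitivity = 0.81, specificity = 0.55),
      "VIA+HPV" = list(sensitivity = 0.58, specificity = 0.84),
      "VIA+Pap" = list(sensitivity = 0.51, specificity = 0.99),
      "HPV+Pap" = list(sensitivity = 0.63, specificity = 0.99)
    ),
    unit_costs = list(
      societal = list(
        screening = c(Pap = 39, VIA = 18, HPV = 32),
        treatment = c(cryotherapy = 48, colposcopy = 160, LEEP = 86),
        side_effects = c(major = 974, minor = 203),
        cancer_care = c(local = 1135, regional = 6447, distant = 5107,
                        palliative_monthly = 196)
      ),
      clinic = list(
        screening = c(Pap = 24, VIA = 10, HPV = 18),
        treatment = c(cryotherapy = 12, colposcopy = 109, LEEP = 20),
        side_effects = c(major = 847, minor = 178),
        cancer_care = c(local = 112, regional = 149, distant = 144,
                        palliative_monthly = 145)
      )
    ),
    discount_monthly = 0.0025,
    p_cryo_given_treatment = 0.8,
    # societal indirect cost per screening episode, by visit structure; used
    # only by the single-visit scenario override
    visit_indirect_cost = c(single_visit = 0.43, multi_visit = 2.88),
    # symptomatic detection of undiagnosed invasive cancer: entering one of
    # these stages triggers staging/treatment with probability 1 that month
    symptomatic_detection = c(local = FALSE, regional = TRUE, distant = TRUE),
    ranges = .default_ranges()
  )
  class(p) <- "cervcost_params"
  validate_parameters(p)
}

# One-way sensitivity ranges, in Table row order. Names are get/set paths
# understood by get_parameter()/set_parameter().
.default_ranges <- function() {
  rg <- list(
    start_age_years = c(30, 46),
    prev_disease = c(0.18, 0.27),
    "split_diseased.HSIL" = c(0.762, 1),
    "split_diseased.local" = c(0.016, 0.024),
    "split_diseased.regional" = c(0.019, 0.029),
    "split_diseased.distant" = c(0.003, 0.005),
    "split_nondiseased.LSIL" = c(0.078, 0.118),
    "split_nondiseased.normal" = c(0.722, 1),
    ltfu_2visit = c(0, 0.4),
    ltfu_3visit = c(0.3, 0.6),
    smr = c(1.42, 2.12),
    "cancer_mortality_monthly.local" = c(0.003, 0.005),
    "cancer_mortality_monthly.regional" = c(0.017, 0.025),
    "cancer_mortality_monthly.distant" = c(0.051, 0.076),
    "progression_monthly.normal_lsil" = c(0.000, 0.002),
    "progression_monthly.lsil_hsil" = c(0.002, 0.004),
    "progression_monthly.hsil_local" = c(0.001, 0.003),
    "progression_monthly.local_regional" = c(0.002, 0.004),
    "progression_monthly.regional_distant" = c(0.002, 0.004),
    "regression_monthly.lsil_normal" = c(0.002, 0.004),
    "regression_monthly.hsil_lsil" = c(0.000, 0.001),
    "regression_monthly.hsil_normal" = c(0.000, 0.001),
    treatment_effectiveness = c(0.7, 1),
    cure_monthly = c(0.12, 0.18),
    side_effect_monthly = c(0.00, 0.02),
    p_side_effect_major = c(0.13, 0.20),
    "sensitivity.Pap" = c(0.59, 0.89),
    "sensitivity.VIA" = c(0.49, 0.73),
    "sensitivity.HPV" = c(0.65, 0.97),
    "sensitivity.VIA+HPV" = c(0.46, 0.70),
    "sensitivity.VIA+Pap" = c(0.41, 0.61),
    "sensitivity.HPV+Pap" = c(0.50, 0.76),
    "specificity.Pap" = c(0.78, 1),
    "specificity.VIA" = c(0.50, 0.76),
    "specificity.HPV" = c(0.44, 0.66),
    "specificity.VIA+HPV" = c(0.67, 1),
    "specificity.VIA+Pap" = c(0.79, 1),
    "specificity.HPV+Pap" = c(0.79, 1),
    "cost.screening.Pap" = c(31, 47),
    "cost.screening.VIA" = c(14, 22),
    "cost.screening.HPV" = c(26, 38),
    "cost.treatment.cryotherapy" = c(38, 58),
    "cost.treatment.colposcopy" = c(128, 192),
    "cost.treatment.LEEP" = c(69, 103),
    "cost.side_effects.major" = c(779, 1169),
    "cost.side_effects.minor" = c(162, 244),
    "cost.cancer_care.local" = c(908, 1362),
    "cost.cancer_care.regional" = c(5158, 7736),
    "cost.cancer_care.distant" = c(4086, 6128),
    "cost.cancer_care.palliative_monthly" = c(157, 235)
  )
  lapply(rg, function(x) c(low = x[[1]], high = x[[2]]))
}

.required_fields <- c(
  "start_age_years", "prev_disease", "split_diseased", "split_nondiseased",
  "ltfu_2visit", "ltfu_3visit", "smr", "cancer_mortality_monthly",
  "progression_monthly", "regression_monthly", "treatment_effectiveness",
  "cure_monthly", "side_effect_monthly", "p_side_effect_major",
  "test_performance", "unit_costs", "discount_monthly",
  "p_cryo_given_treatment"
)

.check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("validation error: ", what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks probability bounds, cost non-negativity, the societal >= clinic
#' ordering of every unit cost, and that every one-way range brackets its
#' base-case value. Split vectors over disease grades are validated
#' componentwise (each share in \[0,1\], positive total); they are treated as
#' weights and renormalized where consumed, which keeps single-component
#' sensitivity excursions valid.
#'
#' @param p A `cervcost_params` object (or bare list with the same fields).
#' @return `p`, invisibly classed, if valid; otherwise an error.
#' @export
validate_parameters <- function(p) {
  missing <- setdiff(.required_fields, names(p))
  if (length(missing))
    stop("schema error: missing parameter field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  .check_prob(p$prev_disease, "prev_disease")
  .check_prob(p$split_diseased, "split_diseased shares")
  .check_prob(p$split_nondiseased, "split_nondiseased shares")
  if (sum(p$split_diseased) <= 0 || sum(p$split_nondiseased) <= 0)
    stop("validation error: split vectors must have positive total weight",
         call. = FALSE)
  .check_prob(c(p$ltfu_2visit, p$ltfu_3visit), "LTFU probabilities")
  if (!is.finite(p$smr) || p$smr <= 0)
    stop("validation error: smr must be > 0", call. = FALSE)
  .check_prob(p$cancer_mortality_monthly, "cancer mortality probabilities")
  .check_prob(p$progression_monthly, "progression probabilities")
  .check_prob(p$regression_monthly, "regression probabilities")
  .check_prob(p$treatment_effectiveness, "treatment_effectiveness")
  .check_prob(p$cure_monthly, "cure_monthly")
  .check_prob(p$side_effect_monthly, "side_effect_monthly")
  .check_prob(p$p_side_effect_major, "p_side_effect_major")
  .check_prob(p$p_cryo_given_treatment, "p_cryo_given_treatment")
  if (!is.finite(p$discount_monthly) || p$discount_monthly < 0)
    stop("validation error: discount_monthly must be >= 0", call. = FALSE)

  for (tn in names(p$test_performance)) {
    tp <- p$test_performance[[tn]]
    .check_prob(c(tp$sensitivity, tp$specificity),
                paste0("test performance for ", tn))
  }

  for (persp in .cost_perspectives) {
    cs <- p$unit_costs[[persp]]
    if (is.null(cs))
      stop("schema error: missing unit_costs for perspective ", persp,
           call. = FALSE)
    for (block in names(cs)) {
      if (any(!is.finite(cs[[block]])) || any(cs[[block]] < 0))
        stop("validation error: ", persp, " ", block,
             " costs must be >= 0", call. = FALSE)
    }
  }
  for (block in names(p$unit_costs$societal)) {
    soc <- p$unit_costs$societal[[block]]
    cli <- p$unit_costs$clinic[[block]][names(soc)]
    if (any(soc < cli - 1e-9))
      stop("validation error: societal unit cost below clinic unit cost in ",
           block, call. = FALSE)
  }

  if (!is.null(p$ranges)) {
    for (nm in names(p$ranges)) {
      r <- p$ranges[[nm]]
      base <- get_parameter(p, nm)
      if (r[["low"]] > base + 1e-9 || r[["high"]] < base - 1e-9)
        stop("validation error: range for ", nm,
             " does not bracket its base value", call. = FALSE)
    }
  }

  class(p) <- "cervcost_params"
  invisible(p)
}

#' @export
print.cervcost_params <- function(x, ...) {
  cat("<cervcost_params>\n")
  cat("  start age:", x$start_age_years, " prevalence:", x$prev_disease,
      " SMR:", x$smr, "\n")
  cat("  LTFU 2-visit:", x$ltfu_2visit, " 3-visit:", x$ltfu_3visit, "\n")
  cat("  tests:", paste(names(x$test_performance), collapse = ", "), "\n")
  cat("  ranged parameters:", length(x$ranges), "\n")
  invisible(x)
}

#' Read a single parameter by path
#'
#' Paths address scalars (`"smr"`), vector components
#' (`"progression_monthly.lsil_hsil"`), test performance
#' (`"sensitivity.HPV"`, `"specificity.Pap"`) and costs by their societal
#' value (`"cost.screening.VIA"`).
#'
#' @param p A `cervcost_params` object.
#' @param name Parameter path.
#' @return The numeric base value.
#' @export
get_parameter <- function(p, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "sensitivity") return(p$test_performance[[parts[2]]]$sensitivity)
  if (parts[1] == "specificity") return(p$test_performance[[parts[2]]]$specificity)
  if (parts[1] == "cost") return(unname(p$unit_costs$societal[[parts[2]]][[parts[3]]]))
  if (length(parts) == 1) return(p[[parts[1]]])
  unname(p[[parts[1]]][[parts[2]]])
}

#' Set a single parameter by path
#'
#' Returns a modified copy; the input is never mutated. A cost path sets the
#' societal value to `value` and scales the clinic value proportionally
#' (one published min-max per cost row covers both perspectives).
#'
#' @inheritParams get_parameter
#' @param value New numeric value.
#' @return A new `cervcost_params` object (not re-validated; callers vary
#'   simplex components singly during sensitivity analysis).
#' @export
set_parameter <- function(p, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "sensitivity") {
    p$test_performance[[parts[2]]]$sensitivity <- value
  } else if (parts[1] == "specificity") {
    p$test_performance[[parts[2]]]$specificity <- value
  } else if (parts[1] == "cost") {
    soc0 <- p$unit_costs$societal[[parts[2]]][[parts[3]]]
    cli0 <- p$unit_costs$clinic[[parts[2]]][[parts[3]]]
    p$unit_costs$societal[[parts[2]]][[parts[3]]] <- value
    p$unit_costs$clinic[[parts[2]]][[parts[3]]] <-
      if (soc0 > 0) cli0 * value / soc0 else cli0
  } else if (length(parts) == 1) {
    p[[parts[1]]] <- value
  } else {
    p[[parts[1]]][[parts[2]]] <- value
  }
  class(p) <- "cervcost_params"
  p
}

#' Load a parameter set from a YAML document
#'
#' The document is a flat, human-editable YAML file with one key per model
#' parameter (see the bundled `parameters_base_case.yaml` under
#' `inst/extdata`). Missing required fields raise a schema error naming the
#' field; out-of-bound values raise a validation error.
#'
#' @param path Path to a YAML parameter document.
#' @return A validated `cervcost_params` object.
#' @export
load_parameters <- function(path) {
  doc <- yaml::read_yaml(path)
  missing <- setdiff(.required_fields, names(doc))
  if (length(missing))
    stop("schema error: missing parameter field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  p <- doc
  for (f in c("split_diseased", "split_nondiseased", "cancer_mortality_monthly",
              "progression_monthly", "regression_monthly",
              "visit_indirect_cost"))
    if (!is.null(p[[f]])) p[[f]] <- unlist(p[[f]])
  if (!is.null(p$symptomatic_detection))
    p$symptomatic_detection <- unlist(p$symptomatic_detection)
  for (persp in names(p$unit_costs))
    p$unit_costs[[persp]] <- lapply(p$unit_costs[[persp]], unlist)
  if (!is.null(p$ranges))
    p$ranges <- lapply(p$ranges, function(x) c(low = x$low, high = x$high))
  defaults <- list(
    visit_indirect_cost = c(single_visit = 0.43, multi_visit = 2.88),
    symptomatic_detection = c(local = FALSE, regional = TRUE, distant = TRUE)
  )
  for (f in names(defaults)) if (is.null(p[[f]])) p[[f]] <- defaults[[f]]
  class(p) <- "cervcost_params"
  validate_parameters(p)
}

#' Write a parameter set to a YAML document
#'
#' Round-trips with [load_parameters()].
#'
#' @param p A `cervcost_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  as_map <- function(x) {  # named atomic vectors must serialize as YAML maps
    if (is.list(x)) lapply(x, as_map)
    else if (!is.null(names(x)) && length(names(x))) as.list(x)
    else x
  }
  doc <- as_map(unclass(p))
  doc$ranges <- lapply(unclass(p)$ranges, function(x)
    list(low = unname(x[["low"]]), high = unname(x[["high"]])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

.scenario_overrides <- list(
  cd4_low = list(
    prev_disease = 0.33,
    # printed shares sum to 1.001; stored as printed, renormalized at use
    split_nondiseased = c(normal = 0.832, LSIL = 0.169),
    smr = 2.54,
    "sensitivity.Pap" = 0.76, "specificity.Pap" = 0.93,
    "sensitivity.VIA" = 0.76, "specificity.VIA" = 0.62,
    "sensitivity.HPV" = 0.92, "specificity.HPV" = 0.46
  ),
  cd4_high = list(
    prev_disease = 0.12,
    split_diseased = c(LSIL = 0, HSIL = 1, local = 0, regional = 0, distant = 0),
    split_nondiseased = c(normal = 0.975, LSIL = 0.025),
    smr = 1.0,
    "progression_monthly.normal_lsil" = 0.000,
    "progression_monthly.lsil_hsil" = 0.001,
    "progression_monthly.hsil_local" = 0.002,
    "sensitivity.Pap" = 0.61, "specificity.Pap" = 0.98,
    "sensitivity.VIA" = 0.52, "specificity.VIA" = 0.73,
    "sensitivity.HPV" = 0.83, "specificity.HPV" = 0.62
  )
)

#' Apply a CD4 scenario to a parameter set
#'
#' Overrides only the cells the scenario specifies (CD4 <= 200 cells/mL or
#' CD4 > 500 cells/mL column); every cell without a scenario value keeps its
#' base-case value. `"base"` returns the input unchanged. Never mutates its
#' input and is idempotent per scenario.
#'
#' @param p A `cervcost_params` object.
#' @param scenario One of `"base"`, `"cd4_low"`, `"cd4_high"`.
#' @return A `cervcost_params` object.
#' @export
apply_scenario <- function(p, scenario = c("base", "cd4_low", "cd4_high")) {
  scenario <- match.arg(scenario)
  if (scenario == "base") return(p)
  ov <- .scenario_overrides[[scenario]]
  for (nm in names(ov)) {
    if (is.vector(ov[[nm]]) && length(ov[[nm]]) > 1) {
      p[[nm]] <- ov[[nm]]
    } else {
      p <- set_parameter(p, nm, ov[[nm]])
    }
  }
  # scenario cells may step outside the base-case one-way brackets
  p$ranges <- NULL
  class(p) <- "cervcost_params"
  p
}

#' Enumerate one-way sensitivity parameter sets
#'
#' One entry per ranged parameter, in the published row order. Each entry's
#' `low_set`/`high_set` differ from `p` in exactly that parameter (for costs,
#' the societal value takes the range endpoint and the clinic value scales
#' proportionally).
#'
#' @param p A validated `cervcost_params` object.
#' @return A list of entries `list(name, low, high, low_set, high_set)`.
#' @export
enumerate_oneway <- function(p) {
  lapply(names(p$ranges), function(nm) {
    r <- p$ranges[[nm]]
    list(name = nm,
         low = unname(r[["low"]]), high = unname(r[["high"]]),
         low_set = set_parameter(p, nm, unname(r[["low"]])),
         high_set = set_parameter(p, nm, unname(r[["high"]])))
  })
}
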