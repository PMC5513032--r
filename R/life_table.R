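#' @title Age-specific background mortality
#' @description
#' Background (all-cause) mortality enters the model as an age-indexed annual
#' probability of death for females, multiplied on the hazard scale by the
#' standardized mortality ratio for treated HIV-infected women. The reference
#' analysis used the WHO age-specific all-cause mortality rates for Kenyan
#' females in 2011; [read_life_table()] ingests such a table exported as CSV,
#' and [synthetic_life_table()] generates a deterministic Gompertz-Makeham
#' stand-in so the full pipeline is testable without external data.
#' @name life_tables
NULL

.new_life_table <- function(ages, q_annual) {
  if (any(diff(ages) <= 0))
    stop("life table error: ages must be strictly increasing", call. = FALSE)
  if (any(!is.finite(q_annual)) || any(q_annual < 0) || any(q_annual > 1))
    stop("life table error: q_annual must lie in [0, 1]", call. = FALSE)
  if (q_annual[length(q_annual)] < 1)
    stop("life table error: q_annual at the final age must be 1 (closure)",
         call. = FALSE)
  structure(data.frame(age = as.integer(ages), q_annual = q_annual),
            class = c("cervcost_life_table", "data.frame"))
}

#' Read a life table from CSV
#'
#' Expects a header row and two columns: integer age and the annual
#' probability of death at that age. Ages must be strictly increasing, all
#' probabilities in \[0,1\], and the final age must carry `q = 1` (the table
#' closure that bounds the model horizon). Queries outside the tabulated age
#' range fail at lookup time, not at load time.
#'
#' @param path CSV file path.
#' @param age_col,q_col Column names (defaults `"age"`, `"q_annual"`).
#' @return A `cervcost_life_table` (a data frame with columns `age`,
#'   `q_annual`).
#' @export
read_life_table <- function(path, age_col = "age", q_col = "q_annual") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(age_col, q_col))
    if (!col %in% names(df))
      stop("life table error: missing column '", col, "'", call. = FALSE)
  .new_life_table(df[[age_col]], df[[q_col]])
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Annual death probability at age x is `1 - exp(-(a + b * c^x))`, clamped to
#' \[0,1\], with `q(age_max) = 1` as closure. Deterministic. The defaults
#' (`a = 0.004`, `b = 4e-5`, `c = 1.095`, ages 30-100) emulate the adult
#' female mortality schedule of a high-HIV-burden East African population
#' around 2011: adult mortality 45q15 of roughly 0.25 and annual death
#' probabilities rising to about 6% by age 80.
#'
#' @param makeham_a Age-independent hazard component (per year), `>= 0`.
#' @param makeham_b Gompertz level parameter (per year), `>= 0`.
#' @param makeham_c Gompertz growth factor per year of age, `> 1`.
#' @param age_min,age_max Integer age span; `age_min < age_max`.
#' @return A `cervcost_life_table`.
#' @export
synthetic_life_table <- function(makeham_a = 0.004, makeham_b = 4e-5,
                                 makeham_c = 1.095,
                                 age_min = 30, age_max = 100) {
  if (makeham_a < 0 || makeham_b < 0 || makeham_c <= 1)
    stop("invalid Gompertz-Makeham parameters: need a >= 0, b >= 0, c > 1",
         call. = FALSE)
  if (age_min >= age_max)
    stop("invalid age span: age_min must be < age_max", call. = FALSE)
  ages <- seq.int(age_min, age_max)
  q <- 1 - exp(-(makeham_a + makeham_b * makeham_c^ages))
  q <- pmin(pmax(q, 0), 1)
  q[length(q)] <- 1
  .new_life_table(ages, q)
}

#' Annual death probability at an age
#'
#' @param lt A `cervcost_life_table`.
#' @param age_years Age in years (fractional ages use the completed year).
#' @return The annual probability of death.
#' @export
annual_mortality <- function(lt, age_years) {
  a <- floor(age_years)
  idx <- match(a, lt$age)
  if (anyNA(idx))
    stop("life table error: age ", paste(a[is.na(idx)], collapse = ", "),
         " outside tabulated range [", lt$age[1], ", ",
         lt$age[nrow(lt)], "]", call. = FALSE)
  lt$q_annual[idx]
}

#' Monthly background mortality with SMR
#'
#' Converts the annual probability of death at the completed age to a monthly
#' probability under a constant hazard within the year, applying the
#' standardized mortality ratio multiplicatively on the hazard scale:
#' `q_m = 1 - (1 - q_annual)^(smr / 12)`. The hazard-scale application keeps
#' `q_m <= 1` for any SMR and matches standard demographic practice.
#'
#' @param lt A `cervcost_life_table`.
#' @param age_years Age in years.
#' @param smr Standardized mortality ratio, `> 0`.
#' @return A monthly probability of death.
#' @export
monthly_background_mortality <- function(lt, age_years, smr) {
  if (smr <= 0) stop("smr must be > 0", call. = FALSE)
  q <- annual_mortality(lt, age_years)
  1 - (1 - q)^(smr / 12)
}
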