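#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% filter mutate group_by summarise ungroup arrange left_join bind_rows select
#' @importFrom rlang .data
NULL

#' Construct an observation table
#'
#' Observations are the model's data: each row is one prevalence or
#' cause-specific-mortality-rate (CSMR) measurement over a closed age
#' interval, for one sex and calendar year, carrying the measured value and
#' an effective sample size (persons for prevalence, person-years for CSMR)
#' used to weight the likelihood.
#'
#' @param measure `"prevalence"` or `"csmr"` per row.
#' @param age_lo,age_hi closed age interval in completed years.
#' @param sex `"male"` or `"female"`.
#' @param year calendar year of the measurement.
#' @param value measured proportion (prevalence) or rate per person-year (csmr).
#' @param effective_n persons or person-years behind the measurement.
#' @return a tibble of class `chd_observations`.
#' @export
observations <- function(measure, age_lo, age_hi, sex, year, value, effective_n) {
  out <- tibble::tibble(
    measure = as.character(measure),
    age_lo = as.integer(age_lo),
    age_hi = as.integer(age_hi),
    sex = as.character(sex),
    year = as.integer(year),
    value = as.numeric(value),
    effective_n = as.numeric(effective_n)
  )
  validate_observations(out)
}

validate_observations <- function(x) {
  stopifnot(all(c("measure", "age_lo", "age_hi", "sex", "year",
                  "value", "effective_n") %in% names(x)))
  if (!all(x$measure %in% c("prevalence", "csmr"))) {
    stop("`measure` must be 'prevalence' or 'csmr'")
  }
  if (!all(x$sex %in% c("male", "female"))) {
    stop("`sex` must be 'male' or 'female'")
  }
  if (any(x$age_lo > x$age_hi)) stop("`age_lo` must be <= `age_hi`")
  if (any(x$value < 0)) stop("observed values must be non-negative")
  if (any(x$effective_n <= 0)) stop("`effective_n` must be positive")
  class(x) <- unique(c("chd_observations", class(x)))
  x
}

#' Convert a survey table to prevalence observations
#'
#' @param survey tibble with columns `age`, `sex`, `year`, `respondents`,
#'   `positives` (the schema written by [simulate_survey()]).
#' @return prevalence observations with `value = positives / respondents` and
#'   `effective_n = respondents`.
#' @export
survey_to_observations <- function(survey) {
  req <- c("age", "sex", "year", "respondents", "positives")
  if (!all(req %in% names(survey))) {
    stop("survey table must have columns ", paste(req, collapse = ", "))
  }
  observations(
    measure = "prevalence",
    age_lo = survey$age, age_hi = survey$age,
    sex = survey$sex, year = survey$year,
    value = survey$positives / survey$respondents,
    effective_n = survey$respondents
  )
}
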