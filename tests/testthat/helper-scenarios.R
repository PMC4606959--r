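# Shared scenario builders for the test suite.

# A small scenario (short death window, coarse knots) used wherever the full
# default scenario's cost is not the point of the test.
small_truth <- function(seed = 1L, ...) {
  make_truth(
    death_years = 1991:2010, survey_years = 1997:2011,
    max_age = 66, seed = seed, ...
  )
}

small_config <- function(...) {
  model_config(age_knot_spacing = 10, year_knot_spacing = 10, ...)
}

truth_observations <- function(truth, sexes = c("male", "female")) {
  obs <- dplyr::bind_rows(
    survey_to_observations(simulate_survey(truth)),
    rates_from_counts(
      simulate_deaths(truth),
      population_from_truth(truth, truth$death_years)
    )
  )
  obs[obs$sex %in% sexes, , drop = FALSE]
}

# Ten-record certificate fixture with a hand-countable split: 7 deaths with
# the condition as underlying cause, 3 with a mention only (underlying is
# something else), across ICD revisions.
records_fixture <- function() {
  tibble::tibble(
    age = c(0L, 0L, 1L, 2L, 45L, 30L, 0L, 5L, 60L, 70L),
    sex = c("male", "female", "male", "female", "male",
            "female", "male", "female", "male", "female"),
    year = c(1970L, 1970L, 1985L, 1985L, 2005L, 2005L, 1970L, 1985L, 2005L, 2005L),
    icd_version = c(8L, 8L, 9L, 9L, 10L, 10L, 8L, 9L, 10L, 10L),
    underlying_cause = c(
      "746.9", "745.4", "745.0", "747.41", "Q21.0",
      "Q24.9", "745.1", "038.9", "I21.9", "I50.0"
    ),
    cause_2 = c("", "", "428.0", "", "", "", "798.0", "745.5", "Q20.3", "Q25.0"),
    cause_3 = c("", "", "", "", "I50.9", "", "", "", "", "")
  )
}
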