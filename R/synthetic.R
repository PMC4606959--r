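#' Synthetic truth scenario
#'
#' Builds a fully specified "truth" for the simulation study: per-sex birth
#' prevalence, a per-sex excess-mortality hazard surface, a deterministic
#' population model, and survey sample sizes. Downstream modules are tested
#' against this known truth. Default parameters mimic the magnitudes of the
#' real US recalled-CHD analysis: birth prevalence 3.29 (males) and 3.23
#' (females) per 1,000; an infant excess hazard near 0.52/yr in 1968
#' declining roughly threefold over four decades (log-linearly in calendar
#' year); a near-flat adult hazard.
#'
#' The hazard is parameterized as
#' `chi(a,t) = (infant_hazard * exp(-a/age_scale) + adult_hazard) *
#'   exp(-decline_rate * (min(t, decline_until) - first_year))`,
#' an age profile peaked at age 0 and near-flat in adulthood, with an
#' optional levelling-off year `decline_until` after which rates are flat in
#' time (the default, the last death year, means the decline runs through the
#' whole window).
#'
#' @param birth_prevalence named numeric, proportion per birth for `male` and
#'   `female`; must lie in (0, 0.05).
#' @param infant_hazard excess hazard at age 0 in the first year, per
#'   person-year.
#' @param adult_hazard asymptotic adult excess hazard, per person-year.
#' @param age_scale e-folding age (years) of the infant hazard peak.
#' @param decline_rate proportional decline of the hazard per calendar year.
#' @param decline_until calendar year after which the hazard is constant in
#'   time; default the last death year (no levelling).
#' @param death_years calendar years with death-certificate data.
#' @param survey_years calendar years with survey prevalence data.
#' @param survey_ages ages (completed years) sampled by the survey; includes
#'   age 0 so the downstream age-0 exclusion rule is exercised.
#' @param survey_cell_size respondents per age/sex/year survey cell.
#' @param max_age oldest single-year age on the grid.
#' @param births0 births per sex in the first death year.
#' @param pop_growth exponential growth rate of births per calendar year.
#' @param seed integer seed governing all random draws from this scenario.
#' @return an object of class `chd_truth`.
#' @export
make_truth <- function(birth_prevalence = c(male = 3.29e-3, female = 3.23e-3),
                       infant_hazard = 0.52,
                       adult_hazard = 0.004,
                       age_scale = 1.5,
                       decline_rate = log(3.2) / 42,
                       decline_until = NULL,
                       death_years = 1968:2010,
                       survey_years = 1997:2011,
                       survey_ages = 0:17,
                       survey_cell_size = 350,
                       max_age = 70,
                       births0 = 1.7e6,
                       pop_growth = 0.007,
                       seed = 1L) {
  if (any(birth_prevalence <= 0) || any(birth_prevalence >= 0.05)) {
    stop("`birth_prevalence` must lie in (0, 0.05)")
  }
  if (!all(c("male", "female") %in% names(birth_prevalence))) {
    stop("`birth_prevalence` must be named with 'male' and 'female'")
  }
  if (infant_hazard <= 0 || adult_hazard <= 0 || age_scale <= 0) {
    stop("hazard parameters must be positive")
  }
  if (decline_rate < 0) stop("`decline_rate` must be non-negative")
  if (births0 <= 0) stop("`births0` must be positive")
  if (is.null(decline_until)) decline_until <- max(death_years)

  years <- seq(min(death_years), max(max(death_years), max(survey_years)))
  grid <- age_time_grid(0:max_age, years)

  tshift <- pmin(years, decline_until) - years[1]
  age_profile <- infant_hazard * exp(-grid$ages / age_scale) + adult_hazard
  chi_vals <- outer(age_profile, exp(-decline_rate * tshift))

  sexes <- list()
  for (s in c("male", "female")) {
    chi <- rate_surface(grid, chi_vals)
    bp <- rep(unname(birth_prevalence[[s]]), length(years))
    sexes[[s]] <- list(
      birth_prevalence = bp,
      chi = chi,
      prevalence = solve_surface(bp, chi)
    )
  }

  structure(list(
    grid = grid,
    sexes = sexes,
    death_years = as.integer(death_years),
    survey_years = as.integer(survey_years),
    survey_ages = as.integer(survey_ages),
    survey_cell_size = survey_cell_size,
    births0 = births0,
    pop_growth = pop_growth,
    first_year = years[1],
    params = list(
      birth_prevalence = birth_prevalence, infant_hazard = infant_hazard,
      adult_hazard = adult_hazard, age_scale = age_scale,
      decline_rate = decline_rate, decline_until = decline_until
    ),
    seed = as.integer(seed)
  ), class = "chd_truth")
}

#' @export
print.chd_truth <- function(x, ...) {
  cat(sprintf(
    "<chd_truth> ages 0-%d, years %d-%d; birth prevalence %.2f/%.2f per 1,000 (m/f), seed %d\n",
    max(x$grid$ages), min(x$grid$years), max(x$grid$years),
    1000 * x$params$birth_prevalence[["male"]],
    1000 * x$params$birth_prevalence[["female"]], x$seed
  ))
  invisible(x)
}

# Deterministic population model: births grow exponentially in calendar time
# and cohorts are thinned by a background (all-cause, non-CHD) survival curve
# with an infant component and a Gompertz old-age component.
background_survival <- function(ages) {
  mu <- 0.006 * exp(-ages) + 2e-4 + 2e-5 * exp(ages / 12)
  exp(-c(0, cumsum(mu[-length(mu)])))
}

#' Population counts implied by a truth scenario
#'
#' @param truth a [make_truth()] scenario.
#' @param years calendar years to cover; defaults to the scenario grid years.
#' @return tibble with columns `age`, `sex`, `year`, `population`.
#' @export
population_from_truth <- function(truth, years = truth$grid$years) {
  ages <- truth$grid$ages
  sbg <- background_survival(ages)
  births <- function(y) truth$births0 * exp(truth$pop_growth * (y - truth$first_year))
  cells <- expand.grid(age = ages, year = as.integer(years))
  n <- pmax(1, round(births(cells$year - cells$age) * sbg[cells$age + 1L]))
  dplyr::bind_rows(
    tibble::tibble(age = cells$age, sex = "male", year = cells$year, population = n),
    tibble::tibble(age = cells$age, sex = "female", year = cells$year, population = n)
  )
}

# One random stream per simulated table: the draw is seeded by (seed, table
# name) so adding a table never perturbs the draws of another, and the
# caller's RNG state is left untouched.
table_offsets <- c(deaths = 101L, survey = 202L, bootstrap = 303L)

with_table_seed <- function(seed, table, expr) {
  off <- table_offsets[[table]]
  s <- (as.integer(seed) %% 1000003L) * 2017L + off
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(s)
  force(expr)
}

#' Simulate a death-count table from a truth scenario
#'
#' For every age/sex/year cell in the death window, the CHD death count is
#' drawn Poisson with mean `N(a,s,t) * p(a,t) * chi(a,t)`, where `p` solves
#' the cohort model on the truth surfaces. The output schema matches the ICD
#' tabulator's output (`age`, `sex`, `year`, `deaths`, `population`) so the
#' two sources are interchangeable downstream.
#'
#' @param truth a [make_truth()] scenario.
#' @return tibble `age`, `sex`, `year`, `deaths`, `population`.
#' @export
simulate_deaths <- function(truth) {
  stopifnot(inherits(truth, "chd_truth"))
  pop <- population_from_truth(truth, truth$death_years)
  yi <- match(pop$year, truth$grid$years)
  ai <- pop$age + 1L
  mu <- numeric(nrow(pop))
  for (s in c("male", "female")) {
    rows <- pop$sex == s
    p <- truth$sexes[[s]]$prevalence$values
    ch <- truth$sexes[[s]]$chi$values
    ij <- cbind(ai[rows], yi[rows])
    mu[rows] <- pop$population[rows] * p[ij] * ch[ij]
  }
  deaths <- with_table_seed(truth$seed, "deaths", stats::rpois(length(mu), mu))
  tibble::tibble(
    age = pop$age, sex = pop$sex, year = pop$year,
    deaths = deaths, population = pop$population
  )
}

#' Simulate a survey prevalence table from a truth scenario
#'
#' Positives are drawn Binomial(respondents, p(a,t)) per age/sex/year cell
#' over the survey window. Age-0 rows are included so the downstream age-0
#' exclusion rule can be exercised.
#'
#' @param truth a [make_truth()] scenario.
#' @return tibble `age`, `sex`, `year`, `respondents`, `positives`.
#' @export
simulate_survey <- function(truth) {
  stopifnot(inherits(truth, "chd_truth"))
  if (any(truth$survey_cell_size <= 0)) stop("survey sample sizes must be positive")
  cells <- expand.grid(
    age = truth$survey_ages, sex = c("male", "female"),
    year = truth$survey_years, stringsAsFactors = FALSE
  )
  yi <- match(cells$year, truth$grid$years)
  ai <- cells$age + 1L
  p <- numeric(nrow(cells))
  for (s in c("male", "female")) {
    rows <- cells$sex == s
    p[rows] <- truth$sexes[[s]]$prevalence$values[cbind(ai[rows], yi[rows])]
  }
  n <- rep(truth$survey_cell_size, length.out = nrow(cells))
  pos <- with_table_seed(truth$seed, "survey", stats::rbinom(nrow(cells), n, p))
  tibble::tibble(
    age = as.integer(cells$age), sex = cells$sex, year = as.integer(cells$year),
    respondents = as.integer(n), positives = pos
  )
}
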