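#' Age-time grid
#'
#' A rectangular grid of single-year ages and calendar years on which hazard
#' and prevalence surfaces are represented. Ages and years must be contiguous
#' integer sequences; the maximum age must be at least 65 so that the 20-64
#' adult band is always inside the grid.
#'
#' @param ages integer vector of ages in completed years, `0:A_max`.
#' @param years integer vector of calendar years, contiguous.
#' @return an object of class `age_time_grid` with elements `ages`, `years`.
#' @export
age_time_grid <- function(ages, years) {
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (length(ages) < 2L || any(diff(ages) != 1L)) {
    stop("`ages` must be a contiguous, strictly increasing integer sequence")
  }
  if (length(years) < 2L || any(diff(years) != 1L)) {
    stop("`years` must be a contiguous, strictly increasing integer sequence")
  }
  if (ages[1] != 0L) stop("`ages` must start at 0")
  if (max(ages) < 65L) stop("grid must extend to at least age 65")
  structure(list(ages = ages, years = years), class = "age_time_grid")
}

#' @export
print.age_time_grid <- function(x, ...) {
  cat(sprintf(
    "<age_time_grid> ages %d-%d, years %d-%d (%d x %d nodes)\n",
    min(x$ages), max(x$ages), min(x$years), max(x$years),
    length(x$ages), length(x$years)
  ))
  invisible(x)
}

grid_dim <- function(grid) c(length(grid$ages), length(grid$years))

same_grid <- function(a, b) {
  identical(a$ages, b$ages) && identical(a$years, b$years)
}

check_surface_values <- function(grid, values) {
  d <- grid_dim(grid)
  if (!is.matrix(values) || !all(dim(values) == d)) {
    stop(sprintf("`values` must be a %d x %d matrix (ages x years)", d[1], d[2]))
  }
  if (any(!is.finite(values))) stop("surface values must be finite")
  invisible(values)
}

#' Hazard surface
#'
#' Excess-mortality hazard \eqn{\chi(a,t)} (per person-year) on an age-time
#' grid; the flow out of the with-condition compartment. Values must be
#' strictly positive and finite.
#'
#' @param grid an [age_time_grid()].
#' @param values numeric matrix, ages x years, hazards per person-year.
#' @return an object of class `rate_surface`.
#' @export
rate_surface <- function(grid, values) {
  check_surface_values(grid, values)
  if (any(values <= 0)) stop("hazard values must be strictly positive")
  structure(list(grid = grid, values = values), class = "rate_surface")
}

#' Prevalence surface
#'
#' With-condition prevalence proportion \eqn{p(a,t)} on an age-time grid,
#' together with the birth prevalence \eqn{p(0,t)} per calendar year (the
#' model's inflow boundary condition).
#'
#' @param grid an [age_time_grid()].
#' @param values numeric matrix, ages x years, proportions in `[0, 1]`.
#' @param birth_prevalence numeric vector, one proportion per grid year.
#' @return an object of class `prevalence_surface`.
#' @export
prevalence_surface <- function(grid, values, birth_prevalence) {
  check_surface_values(grid, values)
  if (any(values < 0 | values > 1)) stop("prevalence values must lie in [0, 1]")
  if (length(birth_prevalence) != length(grid$years)) {
    stop("`birth_prevalence` must have one value per grid year")
  }
  if (any(birth_prevalence < 0 | birth_prevalence > 1)) {
    stop("`birth_prevalence` must lie in [0, 1]")
  }
  structure(
    list(grid = grid, values = values, birth_prevalence = birth_prevalence),
    class = "prevalence_surface"
  )
}

#' @export
print.rate_surface <- function(x, ...) {
  cat(sprintf(
    "<rate_surface> %d x %d, hazard range [%.3g, %.3g] /yr\n",
    nrow(x$values), ncol(x$values), min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
print.prevalence_surface <- function(x, ...) {
  cat(sprintf(
    "<prevalence_surface> %d x %d, birth prevalence %.3g-%.3g\n",
    nrow(x$values), ncol(x$values),
    min(x$birth_prevalence), max(x$birth_prevalence)
  ))
  invisible(x)
}
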