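#' Extend a fit beyond the data window under constant rates
#'
#' Projection conservatively holds birth prevalence and the excess-mortality
#' hazard constant across cohorts after the last fitted year: cohorts born
#' later inherit the final-year birth prevalence, the hazard beyond the
#' window repeats its final-year age profile, and the prevalence surface is
#' re-solved on the extended grid. Within the original window the extended
#' surfaces are identical to the fitted ones (extension is exact, not an
#' approximation, there).
#'
#' @param fit a [fit_map()] result.
#' @param to_year last calendar year of the projection; must be beyond the
#'   fitted window.
#' @return a `chd_fit` whose per-sex surfaces cover the extended grid.
#' @export
extend_constant <- function(fit, to_year) {
  stopifnot(inherits(fit, "chd_fit"))
  out <- fit
  for (s in names(fit$sexes)) {
    f <- fit$sexes[[s]]
    yrs <- f$grid$years
    if (to_year <= max(yrs)) {
      stop("`to_year` must lie beyond the fitted window (", max(yrs), ")")
    }
    new_years <- seq(min(yrs), to_year)
    grid2 <- age_time_grid(f$grid$ages, new_years)
    n_extra <- to_year - max(yrs)
    chi2 <- cbind(f$chi$values,
                  f$chi$values[, rep(ncol(f$chi$values), n_extra)])
    bp2 <- c(f$birth_prevalence,
             rep(f$birth_prevalence[length(f$birth_prevalence)], n_extra))
    chi_s <- rate_surface(grid2, chi2)
    f$grid <- grid2
    f$chi <- chi_s
    f$birth_prevalence <- bp2
    f$prevalence <- solve_surface(bp2, chi_s)
    out$sexes[[s]] <- f
  }
  out$extended_from <- max(fit$sexes[[1]]$grid$years)
  out
}

#' Truncate a fit back to an earlier final year
#'
#' Inverse of [extend_constant()]: restricting an extended fit back to the
#' original window reproduces the original surfaces exactly.
#'
#' @param fit a `chd_fit`.
#' @param to_year new final year (inside the current window).
#' @return the truncated `chd_fit`.
#' @export
truncate_fit <- function(fit, to_year) {
  stopifnot(inherits(fit, "chd_fit"))
  out <- fit
  for (s in names(fit$sexes)) {
    f <- fit$sexes[[s]]
    yrs <- f$grid$years
    if (!to_year %in% yrs) stop("`to_year` outside the current window")
    keep <- yrs <= to_year
    grid2 <- age_time_grid(f$grid$ages, yrs[keep])
    f$grid <- grid2
    f$chi <- rate_surface(grid2, f$chi$values[, keep, drop = FALSE])
    f$birth_prevalence <- f$birth_prevalence[keep]
    f$prevalence <- prevalence_surface(
      grid2, f$prevalence$values[, keep, drop = FALSE], f$birth_prevalence
    )
    out$sexes[[s]] <- f
  }
  out
}

#' Prevalent-population counts
#'
#' Multiplies the prevalence surface by the matching population counts:
#' `count(a, s, t) = p(a, t) * N(a, s, t)`.
#'
#' @param fit a `chd_fit` (possibly extended).
#' @param population tibble `age`, `sex`, `year`, `population`. Years beyond
#'   the population table default to the last observed year's population held
#'   constant, with a warning.
#' @return tibble `age`, `sex`, `year`, `population`, `prevalence`, `count`.
#' @export
prevalent_counts <- function(fit, population) {
  stopifnot(inherits(fit, "chd_fit"))
  out <- list()
  for (s in names(fit$sexes)) {
    f <- fit$sexes[[s]]
    pop_s <- population[population$sex == s, ]
    if (nrow(pop_s) == 0) stop("no population rows for sex ", s)
    missing_years <- setdiff(f$grid$years, unique(pop_s$year))
    if (length(missing_years) > 0) {
      warning("population table ends before the projection horizon for sex ",
              s, "; holding the last observed year's population constant")
      last <- pop_s[pop_s$year == max(pop_s$year), ]
      fill <- do.call(rbind, lapply(missing_years, function(y) {
        transform(last, year = y)
      }))
      pop_s <- rbind(pop_s, fill)
    }
    cells <- expand.grid(age = f$grid$ages, year = f$grid$years)
    ij <- cbind(cells$age + 1L, match(cells$year, f$grid$years))
    key <- paste(pop_s$age, pop_s$year)
    N <- pop_s$population[match(paste(cells$age, cells$year), key)]
    if (any(is.na(N))) stop("population missing for some grid cells (sex ", s, ")")
    p <- f$prevalence$values[ij]
    out[[s]] <- tibble::tibble(
      age = as.integer(cells$age), sex = s, year = as.integer(cells$year),
      population = N, prevalence = p, count = p * N
    )
  }
  dplyr::bind_rows(out)
}

#' Default reporting age bands
#'
#' The bands used throughout: 0 (standing in for 0-51 weeks), 1-4, 5-9,
#' 10-14, 15-19, the 20-64 adult band, and reproductive-age females 15-49.
#'
#' @param adult_hi upper bound (inclusive) of the adult band; 64 by default.
#' @return tibble `band`, `age_lo`, `age_hi`, `sex` (NA = both sexes).
#' @export
default_age_bands <- function(adult_hi = 64L) {
  tibble::tribble(
    ~band,          ~age_lo, ~age_hi,        ~sex,
    "0-51 weeks",   0L,      0L,             NA_character_,
    "1-4",          1L,      4L,             NA_character_,
    "5-9",          5L,      9L,             NA_character_,
    "10-14",        10L,     14L,            NA_character_,
    "15-19",        15L,     19L,            NA_character_,
    "20-64",        20L,     as.integer(adult_hi), NA_character_,
    "female 15-49", 15L,     49L,            "female"
  )
}

#' Aggregate prevalent counts into age bands
#'
#' @param counts output of [prevalent_counts()].
#' @param bands a band table as from [default_age_bands()]; a band with a
#'   non-NA `sex` is restricted to that sex.
#' @param by_sex also split every band by sex (default FALSE: bands pool
#'   sexes unless the band itself is sex-specific).
#' @return tibble `band`, `year`, (`sex`,) `count`, `population`,
#'   `prev_per_1000`.
#' @export
aggregate_bands <- function(counts, bands = default_age_bands(), by_sex = FALSE) {
  out <- list()
  for (i in seq_len(nrow(bands))) {
    sel <- counts$age >= bands$age_lo[i] & counts$age <= bands$age_hi[i]
    if (!is.na(bands$sex[i])) sel <- sel & counts$sex == bands$sex[i]
    sub <- counts[sel, , drop = FALSE]
    if (nrow(sub) == 0) stop("band '", bands$band[i], "' selects no cells")
    grp <- if (by_sex) c("year", "sex") else "year"
    agg <- sub %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
      dplyr::summarise(
        count = sum(.data$count),
        population = sum(.data$population),
        .groups = "drop"
      ) %>%
      dplyr::mutate(
        band = bands$band[i],
        prev_per_1000 = 1000 * .data$count / .data$population
      )
    out[[i]] <- agg
  }
  dplyr::bind_rows(out) %>%
    dplyr::select(dplyr::all_of(c("band", "year",
                                  if (by_sex) "sex",
                                  "count", "population", "prev_per_1000")))
}
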