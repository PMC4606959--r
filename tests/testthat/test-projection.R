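# Constant-rate projection, counts, band aggregation.

make_fitted <- function(seed = 31) {
  tr <- small_truth(seed = seed)
  fit <- fit_map(truth_observations(tr, "male"), small_config())
  list(tr = tr, fit = fit)
}

test_that("extension holds rates constant and is invertible", {
  x <- make_fitted()
  ext <- extend_constant(x$fit, 2050)
  f0 <- x$fit$sexes$male
  f <- ext$sexes$male
  last <- length(f0$birth_prevalence)
  # projected birth prevalence equals the final fitted year's value
  expect_true(all(f$birth_prevalence[(last + 1):length(f$birth_prevalence)] ==
                    f0$birth_prevalence[last]))
  # hazard beyond the window repeats the final-year age profile
  expect_equal(f$chi$values[, ncol(f$chi$values)], f0$chi$values[, last])
  # extend-then-truncate reproduces the original surfaces exactly
  back <- truncate_fit(ext, max(f0$grid$years))
  expect_equal(back$sexes$male$prevalence$values, f0$prevalence$values)
  expect_equal(back$sexes$male$chi$values, f0$chi$values)
  expect_error(extend_constant(x$fit, 2000), "beyond the fitted window")
})

test_that("adult prevalence per capita plateaus under stationary conditions", {
  # hazard decline levels off 20 years before the window end, so rates are
  # already stationary at projection start; the 20-64 band then converges as
  # pre-stabilization cohorts wash out
  tr <- make_truth(decline_until = 1990, seed = 32)
  fit0 <- list(
    sexes = list(male = list(
      grid = tr$grid,
      chi = tr$sexes$male$chi,
      birth_prevalence = tr$sexes$male$birth_prevalence,
      prevalence = tr$sexes$male$prevalence
    )),
    config = model_config()
  )
  class(fit0) <- "chd_fit"
  ext <- extend_constant(fit0, 2055)
  # stationary population: last-year profile held constant
  pop <- population_from_truth(tr, max(tr$grid$years))
  pop <- dplyr::bind_rows(lapply(tr$grid$years[1]:2055, function(y) {
    dplyr::mutate(pop, year = y)
  }))
  counts <- prevalent_counts(ext, pop)
  adult_band <- default_age_bands()[default_age_bands()$band == "20-64", ]
  adult <- aggregate_bands(counts, adult_band)
  # 40 years past the 2011 window end: year-over-year relative change < 0.1%
  p50 <- adult$prev_per_1000[adult$year == 2051]
  p51 <- adult$prev_per_1000[adult$year == 2052]
  expect_lt(abs(p51 / p50 - 1), 0.001)
  # and the adult prevalence grew substantially before flattening
  expect_gt(p50 / adult$prev_per_1000[adult$year == 1970], 1.3)
})

test_that("counts are products of prevalence and population", {
  x <- make_fitted(33)
  pop <- population_from_truth(x$tr, x$fit$sexes$male$grid$years)
  counts <- prevalent_counts(x$fit, pop)
  expect_true(all(counts$count >= 0 & counts$count <= counts$population))
  i <- which(counts$age == 30 & counts$year == 2005)[1]
  f <- x$fit$sexes$male
  expect_equal(counts$count[i],
               f$prevalence$values[31, match(2005, f$grid$years)] *
                 counts$population[i])
})

test_that("projection without a projected population warns and holds it", {
  x <- make_fitted(34)
  ext <- extend_constant(x$fit, 2020)
  pop <- population_from_truth(x$tr, x$fit$sexes$male$grid$years)
  expect_warning(counts <- prevalent_counts(ext, pop), "holding the last")
  n2011 <- counts$population[counts$age == 40 & counts$year == max(x$fit$sexes$male$grid$years)]
  n2020 <- counts$population[counts$age == 40 & counts$year == 2020]
  expect_equal(n2011, n2020)
})

test_that("band aggregation sums cells and conserves totals", {
  x <- make_fitted(35)
  pop <- population_from_truth(x$tr, x$fit$sexes$male$grid$years)
  counts <- prevalent_counts(x$fit, pop)
  male_bands <- default_age_bands()[default_age_bands()$band != "female 15-49", ]
  bands <- aggregate_bands(counts, male_bands)
  yr <- 2005
  # 20-64 band equals the brute-force sum over single ages
  manual <- sum(counts$count[counts$age >= 20 & counts$age <= 64 & counts$year == yr])
  expect_equal(bands$count[bands$band == "20-64" & bands$year == yr], manual)
  # single-age band equals that age's count
  expect_equal(
    bands$count[bands$band == "0-51 weeks" & bands$year == yr],
    sum(counts$count[counts$age == 0 & counts$year == yr])
  )
  # a partition of the full age range conserves the total
  part <- tibble::tibble(
    band = c("a", "b", "c"), age_lo = c(0L, 20L, 65L),
    age_hi = c(19L, 64L, 66L), sex = NA_character_
  )
  pb <- aggregate_bands(counts, part)
  expect_equal(sum(pb$count[pb$year == yr]), sum(counts$count[counts$year == yr]))
  # female-only band on a male-only fit selects nothing
  expect_error(
    aggregate_bands(counts, default_age_bands()[7, ]),
    "selects no cells"
  )
  # two equal-population ages at 1 and 3 per 1,000 average to 2 per 1,000
  toy <- tibble::tibble(
    age = c(10L, 11L), sex = "male", year = 2000L,
    population = c(1e5, 1e5), prevalence = c(1e-3, 3e-3),
    count = c(100, 300)
  )
  tb <- aggregate_bands(toy, tibble::tibble(
    band = "pair", age_lo = 10L, age_hi = 11L, sex = NA_character_
  ))
  expect_equal(tb$prev_per_1000, 2)
})
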