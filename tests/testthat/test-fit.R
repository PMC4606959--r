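# Penalized MAP fitting: predictions, gradient, recovery, bookkeeping.

test_that("interval predictions aggregate the surfaces correctly", {
  grid <- age_time_grid(0:70, 2000:2005)
  pvals <- matrix(0.003, 71, 6)
  pvals[21, 3] <- 0.002; pvals[22, 3] <- 0.004
  p <- prevalence_surface(grid, pvals, rep(0.003, 6))
  chi <- rate_surface(grid, matrix(0.177, 71, 6))
  # degenerate single-age interval
  o1 <- observations("prevalence", 30, 30, "male", 2001, 0.001, 100)
  expect_equal(predict_observation(o1, p, chi), 0.003)
  # symmetric mean over two equally weighted ages
  o2 <- observations("prevalence", 20, 21, "male", 2002, 0.001, 100)
  expect_equal(predict_observation(o2, p, chi), 0.003)
  # csmr is the product p * chi (here 53.1 per 100,000 person-years)
  o3 <- observations("csmr", 30, 30, "male", 2001, 0.001, 100)
  expect_equal(predict_observation(o3, p, chi), 0.003 * 0.177)
  # population weighting shifts the interval mean
  pop <- tibble::tibble(age = c(20L, 21L), sex = "male", year = 2002L,
                        population = c(3e6, 1e6))
  expect_equal(predict_observation(o2, p, chi, pop),
               (3 * 0.002 + 1 * 0.004) / 4)
  expect_error(predict_observation(
    observations("prevalence", 60, 75, "male", 2001, 0.001, 100), p, chi
  ), "outside grid")
})

test_that("analytic gradient matches central finite differences", {
  tr <- small_truth(seed = 21)
  obs <- truth_observations(tr, "male")
  cfg <- small_config()
  o <- obs[!(obs$measure == "prevalence" & obs$age_lo == 0L), ]
  grid <- age_time_grid(0:66, seq(min(o$year), max(o$year)))
  objf <- chdprev:::make_objective_split(o, grid, cfg)
  n <- objf$n_p0 + objf$Ka * objf$Kt
  set.seed(31)
  for (rep in 1:2) {
    theta <- c(log(3e-3), rep(log(0.05), n - 1)) + rnorm(n, 0, 0.3)
    g <- objf$gr(theta)
    idx <- sample(n, 12)
    h <- 1e-5
    gfd <- vapply(idx, function(i) {
      tp <- theta; tm <- theta
      tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      (objf$fn(tp) - objf$fn(tm)) / (2 * h)
    }, numeric(1))
    expect_equal(g[idx], gfd, tolerance = 1e-4)
  }
})

test_that("noise-free data inside the model family are recovered to <1%", {
  # truth: log-affine hazard (reproduced exactly by the knot basis) and
  # constant birth prevalence; observations set to exact model predictions
  grid <- age_time_grid(0:66, 1997:2011)
  bp_true <- 3.0e-3
  chi_true <- rate_surface(
    grid, outer(0:66, 1997:2011, function(a, t) exp(-3 - 0.02 * a - 0.01 * (t - 1997)))
  )
  p_true <- solve_surface(bp_true, chi_true)
  cells <- expand.grid(age = 1:17, year = 1997:2011)
  prev_obs <- observations(
    "prevalence", cells$age, cells$age, "male", cells$year,
    p_true$values[cbind(cells$age + 1, match(cells$year, grid$years))],
    effective_n = 1e6
  )
  cells2 <- expand.grid(age = 0:66, year = 1997:2011)
  ij <- cbind(cells2$age + 1, match(cells2$year, grid$years))
  csmr_obs <- observations(
    "csmr", cells2$age, cells2$age, "male", cells2$year,
    p_true$values[ij] * chi_true$values[ij],
    effective_n = 1e7
  )
  fit <- fit_map(rbind(prev_obs, csmr_obs),
                 small_config(max_age = 66, years = 1997:2011))
  f <- fit$sexes$male
  expect_true(f$converged)
  expect_lt(abs(f$birth_prevalence[1] / bp_true - 1), 0.01)
  expect_lt(max(abs(f$chi$values / chi_true$values - 1)), 0.05)
})

test_that("objective decomposition is exact bookkeeping", {
  tr <- small_truth(seed = 22)
  fit <- fit_map(truth_observations(tr, "male"), small_config())
  f <- fit$sexes$male
  expect_equal(f$objective, -f$loglik + f$penalty, tolerance = 1e-8)
  # the reported loglik equals the exported likelihood evaluated at the fit
  ll <- sum(loglik_offset_lognormal(
    f$residuals$value, f$residuals$predicted, f$residuals$effective_n,
    f$residuals$delta, fit$config$dispersion, moment_correct = TRUE
  ))
  expect_equal(f$loglik, ll, tolerance = 1e-8)
})

test_that("fitted surfaces satisfy the model invariants", {
  tr <- small_truth(seed = 23)
  fit <- fit_map(truth_observations(tr), small_config())
  for (s in c("male", "female")) {
    f <- fit$sexes[[s]]
    expect_true(all(f$chi$values > 0))
    p <- f$prevalence$values
    expect_true(all(p >= 0 & p <= 1))
    nA <- nrow(p); nT <- ncol(p)
    expect_true(all(p[-1, -1] - p[-nA, -nT] <= 1e-15))  # cohort monotone
  }
})

test_that("age-zero prevalence rows are excluded by default but usable", {
  tr <- small_truth(seed = 24)
  obs <- truth_observations(tr, "male")
  fit <- fit_map(obs, small_config())
  res <- fit$sexes$male$residuals
  expect_false(any(res$measure == "prevalence" & res$age_lo == 0))
  fit2 <- fit_map(obs, small_config(exclude_age_zero_prevalence = FALSE))
  res2 <- fit2$sexes$male$residuals
  expect_true(any(res2$measure == "prevalence" & res2$age_lo == 0))
})

test_that("a sex without both data streams is an error", {
  tr <- small_truth(seed = 25)
  obs <- truth_observations(tr, "male")
  expect_error(fit_map(obs[obs$measure == "csmr", ], small_config()),
               "at least one prevalence")
})

test_that("time-varying birth prevalence reduces to the constant fit shape", {
  tr <- small_truth(seed = 26)
  obs <- truth_observations(tr, "male")
  fit <- fit_map(obs, small_config(constant_birth_prevalence = FALSE))
  f <- fit$sexes$male
  expect_true(f$converged)
  expect_equal(length(unique(round(f$birth_prevalence, 10))) > 1, TRUE)
  # stays in the neighbourhood of the constant-truth value throughout
  expect_true(all(abs(f$birth_prevalence / 3.29e-3 - 1) < 0.35))
})
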