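#' Parametric-bootstrap uncertainty intervals
#'
#' For each replicate, new observation values are drawn from the fitted
#' offset log-normal data model centred at the point-estimate predictions
#' (same per-observation variance as the likelihood), the model is refit
#' (warm-started from the point estimate), and all quantities of interest
#' are recomputed per replicate. Intervals are percentile-based
#' (2.5th/97.5th). Replicates whose refit does not converge are dropped and
#' logged; more than 20% dropped is a hard error.
#'
#' @param fit a converged [fit_map()] result.
#' @param obs the observation table the fit used.
#' @param config the [model_config()] of the fit.
#' @param n_reps number of bootstrap replicates (>= 2). Default 1000 for
#'   production use; simulation studies in the tests use far fewer.
#' @param seed integer seed; the same seed and `n_reps` give identical
#'   intervals.
#' @param population optional population table (as in [fit_map()]).
#' @param noise_scale multiplier on the data-model SD when resampling;
#'   1 is the fitted model, smaller values shrink the intervals toward the
#'   point fit (0 gives degenerate replicates).
#' @return an object of class `chd_bootstrap`: the point `fit`, per-sex
#'   matrices of replicate birth-prevalence paths, replicate knot parameters
#'   (from which any derived quantity can be reconstructed per replicate),
#'   and 95% percentile intervals for birth prevalence.
#' @export
bootstrap_fit <- function(fit, obs, config = fit$config, n_reps = 1000L,
                          seed = 1L, population = NULL, noise_scale = 1) {
  stopifnot(inherits(fit, "chd_fit"))
  if (n_reps < 2L) stop("`n_reps` must be at least 2")
  for (s in names(fit$sexes)) {
    if (!fit$sexes[[s]]$converged) {
      stop("point fit for sex ", s, " did not converge; refusing to bootstrap")
    }
  }
  obs <- validate_observations(tibble::as_tibble(obs))
  if (config$exclude_age_zero_prevalence) {
    obs <- obs[!(obs$measure == "prevalence" & obs$age_lo == 0L &
                   obs$age_hi == 0L), , drop = FALSE]
  }

  reps <- list()
  for (s in names(fit$sexes)) {
    f <- fit$sexes[[s]]
    o <- f$residuals            # carries predicted, delta, data-model moments
    sdl <- sqrt(o$s2) * noise_scale
    mu <- o$mu_log
    thetas <- matrix(NA_real_, length(f$theta), n_reps)
    bps <- matrix(NA_real_, length(f$birth_prevalence), n_reps)
    ok <- logical(n_reps)
    # one objective structure per sex; only the data values change between
    # replicates. Pseudo-data are passed on the model's log scale,
    # untruncated: censoring draws below -delta at zero would shift the
    # refit data upward and bias the intervals.
    objf <- make_objective_split(
      o[, c("measure", "age_lo", "age_hi", "sex", "year",
            "value", "effective_n")],
      f$grid, config, population
    )
    lb <- c(rep(config$log_bounds$p0[1], objf$n_p0),
            rep(config$log_bounds$chi[1], objf$Ka * objf$Kt))
    ub <- c(rep(config$log_bounds$p0[2], objf$n_p0),
            rep(config$log_bounds$chi[2], objf$Ka * objf$Kt))
    for (r in seq_len(n_reps)) {
      draw <- with_table_seed(seed + 7L * r + match(s, c("male", "female")),
                              "bootstrap",
                              stats::rnorm(length(mu), mu, sdl))
      objf$set_log_obs(draw)
      # replicate refits are warm-started at the point estimate and use a
      # slightly looser relative-reduction stop than the point fit
      opt <- try(stats::optim(
        f$theta, objf$fn, objf$gr, method = "L-BFGS-B",
        lower = lb, upper = ub,
        control = list(maxit = config$maxit, pgtol = config$grad_tol,
                       factr = 1e9)
      ), silent = TRUE)
      if (inherits(opt, "try-error") || opt$convergence != 0L) next
      e <- objf$forward(opt$par)
      thetas[, r] <- opt$par
      bps[, r] <- exp(e$lbp_years)
      ok[r] <- TRUE
    }
    if (mean(!ok) > 0.2) {
      stop(sprintf("%.0f%% of bootstrap replicates failed for sex %s",
                   100 * mean(!ok), s))
    }
    if (any(!ok)) {
      message(sum(!ok), " bootstrap replicate(s) dropped for sex ", s)
    }
    bps <- bps[, ok, drop = FALSE]
    reps[[s]] <- list(
      theta = thetas[, ok, drop = FALSE],
      birth_prevalence = bps,
      n_dropped = sum(!ok),
      ui_lower = apply(bps, 1, stats::quantile, probs = 0.025, names = FALSE),
      ui_upper = apply(bps, 1, stats::quantile, probs = 0.975, names = FALSE)
    )
  }
  structure(list(
    fit = fit, replicates = reps, n_reps = n_reps, seed = seed,
    noise_scale = noise_scale
  ), class = "chd_bootstrap")
}

#' 95% uncertainty interval for birth prevalence
#'
#' @param boot a [bootstrap_fit()] result.
#' @param sex which sex; default both.
#' @param year calendar year; default the last fitted year.
#' @return tibble `sex`, `year`, `estimate`, `lower`, `upper` (proportions).
#' @export
birth_prevalence_ui <- function(boot, sex = names(boot$replicates),
                                year = NULL) {
  out <- lapply(sex, function(s) {
    f <- boot$fit$sexes[[s]]
    yrs <- f$grid$years
    y <- if (is.null(year)) max(yrs) else year
    i <- match(y, yrs)
    if (is.na(i)) stop("year outside fitted window")
    r <- boot$replicates[[s]]
    tibble::tibble(
      sex = s, year = y,
      estimate = f$birth_prevalence[i],
      lower = r$ui_lower[i],
      upper = r$ui_upper[i]
    )
  })
  dplyr::bind_rows(out)
}

#' Recompute a derived quantity for every bootstrap replicate
#'
#' Applies `fun(prevalence_surface, chi_surface)` to the surfaces implied by
#' each replicate's knot parameters and returns the replicate values, so
#' percentile intervals of nonlinear aggregates (counts, band prevalences)
#' are formed on the derived scale, never by transforming surface intervals.
#'
#' @param boot a [bootstrap_fit()] result.
#' @param sex sex to evaluate.
#' @param fun function of `(p, chi)` returning a numeric scalar or vector.
#' @return matrix with one column per surviving replicate.
#' @export
bootstrap_derived <- function(boot, sex, fun) {
  f <- boot$fit$sexes[[sex]]
  th <- boot$replicates[[sex]]$theta
  vapply(seq_len(ncol(th)), function(r) {
    e <- f$objf$forward(th[, r])
    p <- prevalence_surface(f$grid, e$p, exp(e$lbp_years))
    chi <- rate_surface(f$grid, e$chi)
    as.numeric(fun(p, chi))
  }, numeric(length(fun(f$prevalence, f$chi))))
}
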