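#' Model configuration
#'
#' Collects the tunable settings of the penalized MAP fit.
#'
#' @param smoothing_sigma scale of the second-order smoothing penalty applied
#'   to the log-hazard surface (age, cohort and cross directions); default 1.
#' @param offset_delta likelihood offset; `NULL` (default) sets it per
#'   measure type to one count at the median effective sample size (see
#'   [default_offset()]). A single value or a named vector
#'   `c(prevalence = , csmr = )` overrides it.
#' @param dispersion global log-scale residual SD added to each observation's
#'   delta-method sampling variance.
#' @param age_knot_spacing,year_knot_spacing knot spacing (years) of the
#'   log-hazard basis; age knots are densified in childhood (0, 1, 5) where
#'   the hazard is steep.
#' @param exclude_age_zero_prevalence drop age-0 prevalence observations
#'   before fitting (avoids age-differential response bias; default TRUE).
#' @param constant_birth_prevalence constrain birth prevalence to a single
#'   value per sex over all years (default TRUE); when FALSE it varies by
#'   birth year on the year-knot basis with its own second-difference
#'   penalty.
#' @param max_age,years grid extent; `NULL` infers from the observations.
#' @param maxit iteration cap of the bounded quasi-Newton optimizer.
#' @param grad_tol projected-gradient tolerance (`pgtol` of L-BFGS-B).
#' @param log_bounds length-2 list of lower/upper bounds on the log-scale
#'   parameters (birth prevalence, hazard).
#' @return a list of class `chd_config`.
#' @export
model_config <- function(smoothing_sigma = 1,
                         offset_delta = NULL,
                         dispersion = 0.1,
                         age_knot_spacing = 5,
                         year_knot_spacing = 5,
                         exclude_age_zero_prevalence = TRUE,
                         constant_birth_prevalence = TRUE,
                         max_age = NULL,
                         years = NULL,
                         maxit = 1000L,
                         grad_tol = 1e-8,
                         log_bounds = list(
                           p0 = log(c(1e-6, 0.05)),
                           chi = log(c(1e-8, 5))
                         )) {
  if (smoothing_sigma <= 0) stop("`smoothing_sigma` must be positive")
  if (!is.null(offset_delta) && any(offset_delta <= 0)) {
    stop("`offset_delta` must be positive")
  }
  if (dispersion < 0) stop("`dispersion` must be non-negative")
  structure(as.list(environment()), class = "chd_config")
}

# Linear-interpolation basis matrix: points x knots, rows sum to 1; points
# outside the knot range are clamped to the boundary knot.
interp_basis <- function(points, knots) {
  K <- length(knots)
  if (K == 1L) return(matrix(1, length(points), 1L))
  M <- matrix(0, length(points), K)
  j <- pmin(pmax(findInterval(points, knots), 1L), K - 1L)
  w <- (points - knots[j]) / (knots[j + 1L] - knots[j])
  w <- pmin(pmax(w, 0), 1)
  M[cbind(seq_along(points), j)] <- 1 - w
  M[cbind(seq_along(points), j + 1L)] <- M[cbind(seq_along(points), j + 1L)] + w
  M
}

default_age_knots <- function(max_age, spacing) {
  sort(unique(c(0, 1, 5, seq(10, max_age, by = spacing), max_age)))
}

default_year_knots <- function(years, spacing) {
  sort(unique(c(seq(min(years), max(years), by = spacing), max(years))))
}

#' Predict an observation from model surfaces
#'
#' Prevalence predictions are the population-weighted mean of `p(a, t)` over
#' the observation's closed age interval at its year and sex; CSMR
#' predictions are the population-weighted mean of `p(a,t) * chi(a,t)`
#' (every cause-coded death is an excess death among prevalent cases).
#'
#' @param obs an observation table ([observations()]).
#' @param p a [prevalence_surface()].
#' @param chi a [rate_surface()] on the same grid.
#' @param population tibble `age`, `sex`, `year`, `population`; `NULL` gives
#'   equal weights within the interval.
#' @return numeric vector of predicted values, one per observation row.
#' @export
predict_observation <- function(obs, p, chi, population = NULL) {
  if (!same_grid(p$grid, chi$grid)) stop("surfaces must share a grid")
  grid <- p$grid
  pc <- p$values * chi$values
  vapply(seq_len(nrow(obs)), function(i) {
    ages <- obs$age_lo[i]:obs$age_hi[i]
    ai <- match(ages, grid$ages)
    ti <- match(obs$year[i], grid$years)
    if (any(is.na(ai)) || is.na(ti)) {
      stop(sprintf("observation interval [%d,%d] x %d outside grid",
                   obs$age_lo[i], obs$age_hi[i], obs$year[i]))
    }
    w <- rep(1, length(ages))
    if (!is.null(population)) {
      m <- population[population$sex == obs$sex[i] &
                        population$year == obs$year[i], ]
      w <- m$population[match(ages, m$age)]
      if (any(is.na(w))) stop("population missing for observation interval")
    }
    w <- w / sum(w)
    if (obs$measure[i] == "prevalence") {
      sum(w * p$values[ai, ti])
    } else {
      sum(w * pc[ai, ti])
    }
  }, numeric(1))
}

# ---- internal objective with analytic gradient --------------------------

# Builds the per-sex penalized negative log-posterior and its gradient over
# theta = c(log birth-prevalence knots, vec(log chi knots)). The forward pass
# is cached so optim's alternating fn/gr calls cost one pass per iterate.
make_objective_split <- function(obs, grid, config, population = NULL) {
  nA <- length(grid$ages)
  nT <- length(grid$years)
  age_knots <- default_age_knots(max(grid$ages), config$age_knot_spacing)
  year_knots <- default_year_knots(grid$years, config$year_knot_spacing)
  Ba <- interp_basis(grid$ages, age_knots)
  Bt <- interp_basis(grid$years, year_knots)
  Ka <- ncol(Ba)
  Kt <- ncol(Bt)
  n_p0 <- if (config$constant_birth_prevalence) 1L else Kt
  Bt0 <- if (n_p0 > 1L) Bt else matrix(1, nT, 1L)

  P <- penalty_matrix(nA, nT)
  sigma2 <- config$smoothing_sigma^2
  # penalty on the (log) birth-prevalence path when it varies in time
  Dp0 <- if (n_p0 > 1L && nT >= 3L) {
    diff(diag(nT), differences = 2)
  } else NULL

  # per-measure offsets: one count at the measure's median effective n
  deltas <- vapply(c("prevalence", "csmr"), function(m) {
    d <- config$offset_delta
    if (!is.null(d)) {
      if (length(d) == 2L && !is.null(names(d))) return(d[[m]]) else return(d[[1]])
    }
    default_offset(obs$effective_n[obs$measure == m])
  }, numeric(1))

  obs$delta <- deltas[obs$measure]
  obs$log_obs <- log(obs$value + obs$delta)
  log_obs <- obs$log_obs

  # sparse interval-aggregation weights, one row per observation
  W_rows <- integer(0); W_cols <- integer(0); W_vals <- numeric(0)
  for (i in seq_len(nrow(obs))) {
    ages <- obs$age_lo[i]:obs$age_hi[i]
    ai <- match(ages, grid$ages)
    ti <- match(obs$year[i], grid$years)
    if (any(is.na(ai)) || is.na(ti)) {
      stop(sprintf("observation interval [%d,%d] x %d outside grid",
                   obs$age_lo[i], obs$age_hi[i], obs$year[i]))
    }
    w <- rep(1, length(ages))
    if (!is.null(population) && length(ages) > 1L) {
      m <- population[population$sex == obs$sex[i] &
                        population$year == obs$year[i], ]
      w <- m$population[match(ages, m$age)]
      if (any(is.na(w))) stop("population missing for observation interval")
    }
    W_rows <- c(W_rows, rep(i, length(ages)))
    W_cols <- c(W_cols, ai + (ti - 1L) * nA)
    W_vals <- c(W_vals, w / sum(w))
  }
  W <- Matrix::sparseMatrix(i = W_rows, j = W_cols, x = W_vals,
                            dims = c(nrow(obs), nA * nT))
  is_prev <- obs$measure == "prevalence"
  Wp <- W[is_prev, , drop = FALSE]
  Wc <- W[!is_prev, , drop = FALSE]
  Wpt <- Matrix::t(Wp)
  Wct <- Matrix::t(Wc)

  ci <- pmax(outer(seq_len(nA), seq_len(nT), function(a, t) t - a + 1L), 1L)
  ci_vec <- as.vector(ci)
  ci_levels <- sort(unique(ci_vec))
  ci_fac <- match(ci_vec, ci_levels)

  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL

  forward <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return(cache)
    lp0_k <- theta[seq_len(n_p0)]
    Theta <- matrix(theta[-seq_len(n_p0)], Ka, Kt)
    L <- Ba %*% Theta %*% t(Bt)
    chi <- exp(L)
    C <- cumulative_hazard_grid(L)
    lbp_years <- as.vector(Bt0 %*% lp0_k)
    logp <- matrix(lbp_years[ci], nA, nT) - C
    p <- exp(logp)
    pv <- as.vector(p)
    sv <- pv * as.vector(chi)          # p * chi, vectorised
    pred <- numeric(nrow(obs))
    pred[is_prev] <- as.vector(Wp %*% pv)
    pred[!is_prev] <- as.vector(Wc %*% sv)
    mm <- data_model_moments(pred, obs$effective_n, obs$delta,
                             config$dispersion)
    r <- log_obs - mm$m
    nll <- sum(0.5 * log(2 * pi * mm$s2) + r^2 / (2 * mm$s2))
    Lv <- as.vector(L)
    PL <- as.vector(P %*% Lv)
    pen <- sum(Lv * PL) / (2 * sigma2)
    if (!is.null(Dp0)) {
      d2 <- Dp0 %*% lbp_years
      pen <- pen + sum(d2^2) / (2 * sigma2)
    }
    cache$theta <- theta
    cache$L <- L; cache$chi <- chi; cache$C <- C
    cache$logp <- logp; cache$p <- p; cache$pred <- pred; cache$r <- r
    cache$mm <- mm
    cache$nll <- nll; cache$pen <- pen; cache$PL <- PL
    cache$lbp_years <- lbp_years
    cache$value <- nll + pen
    cache
  }

  fn <- function(theta) forward(theta)$value

  gr <- function(theta) {
    e <- forward(theta)
    qd <- e$pred + obs$delta
    dV <- (obs$delta - e$pred) / (obs$effective_n * qd^3)
    dm <- 1 / qd - dV / 2
    s2 <- e$mm$s2
    dpred <- 0.5 * dV / s2 - e$r * dm / s2 - e$r^2 * dV / (2 * s2^2)
    chiv <- as.vector(e$chi)
    pv <- as.vector(e$p)
    gW_prev <- as.vector(Wpt %*% dpred[is_prev])
    gW_csmr <- as.vector(Wct %*% dpred[!is_prev])
    g_pv <- gW_prev + gW_csmr * chiv
    gL_direct <- gW_csmr * pv * chiv
    Glogp <- matrix(g_pv * pv, nA, nT)

    # birth prevalence
    g_lbp_years <- as.vector(rowsum(as.vector(Glogp), ci_fac, reorder = TRUE))
    full <- numeric(nT); full[ci_levels] <- g_lbp_years
    if (!is.null(Dp0)) {
      full <- full + as.vector(crossprod(Dp0, Dp0 %*% e$lbp_years)) / sigma2
    }
    g_p0 <- as.vector(crossprod(Bt0, full))

    # back-propagate through the cumulative hazard recursion
    A <- -Glogp
    if (nT > 1L) {
      for (a in seq(nA - 1L, 1L)) {
        A[a, 1:(nT - 1L)] <- A[a, 1:(nT - 1L)] + A[a + 1L, 2:nT]
      }
    }
    GL <- matrix(gL_direct, nA, nT)
    if (nT > 1L) {
      H <- exp((e$L[-nA, -nT, drop = FALSE] + e$L[-1, -1, drop = FALSE]) / 2)
      M <- A[-1, -1, drop = FALSE] * H / 2
      GL[-nA, -nT] <- GL[-nA, -nT] + M
      GL[-1, -1] <- GL[-1, -1] + M
    }
    He <- exp((e$L[-nA, 1] + e$L[-1, 1]) / 2)
    GHe <- rev(cumsum(rev(A[-1, 1])))
    Me <- GHe * He / 2
    GL[-nA, 1] <- GL[-nA, 1] + Me
    GL[-1, 1] <- GL[-1, 1] + Me

    GL <- GL + matrix(e$PL / sigma2, nA, nT)
    g_chi <- as.vector(t(Ba) %*% GL %*% Bt)
    c(g_p0, g_chi)
  }

  # swap in new log-scale data (parametric-bootstrap pseudo-data) without
  # rebuilding the weight and penalty structures; `y` is log(value + delta)
  set_log_obs <- function(y) {
    log_obs <<- y
    cache$theta <- NULL
    invisible(NULL)
  }

  list(
    fn = fn, gr = gr, forward = forward, set_log_obs = set_log_obs,
    n_p0 = n_p0, Ka = Ka, Kt = Kt,
    age_knots = age_knots, year_knots = year_knots,
    Ba = Ba, Bt = Bt, Bt0 = Bt0, ci = ci,
    deltas = deltas, obs = obs, grid = grid
  )
}

#' Fit birth prevalence and excess mortality by penalized MAP
#'
#' Maximizes the offset log-normal likelihood minus the second-order
#' smoothing penalties over log-parameterized birth prevalence and hazard
#' knot values, separately per sex, with a bounded quasi-Newton optimizer
#' (L-BFGS-B) started deterministically from flat surfaces at the empirical
#' crude rates.
#'
#' @param obs an observation table with at least one prevalence and one CSMR
#'   observation per sex present.
#' @param config a [model_config()].
#' @param population optional population table used to weight multi-age
#'   observation intervals.
#' @return an object of class `chd_fit`: per-sex `prevalence` and `chi`
#'   surfaces, knot parameters, and an objective decomposition
#'   (`objective = -loglik + penalty`), plus convergence diagnostics.
#' @export
fit_map <- function(obs, config = model_config(), population = NULL) {
  obs <- validate_observations(tibble::as_tibble(obs))
  if (config$exclude_age_zero_prevalence) {
    obs <- obs[!(obs$measure == "prevalence" & obs$age_lo == 0L &
                   obs$age_hi == 0L), , drop = FALSE]
  }
  sexes <- sort(unique(obs$sex))
  fits <- list()
  for (s in sexes) {
    o <- obs[obs$sex == s, , drop = FALSE]
    if (!any(o$measure == "prevalence") || !any(o$measure == "csmr")) {
      stop("need at least one prevalence and one csmr observation for sex ", s)
    }
    fits[[s]] <- fit_one_sex(o, config, population)
  }
  structure(list(sexes = fits, config = config), class = "chd_fit")
}

fit_one_sex <- function(o, config, population) {
  max_age <- if (is.null(config$max_age)) max(o$age_hi) else config$max_age
  years <- if (is.null(config$years)) seq(min(o$year), max(o$year)) else config$years
  grid <- age_time_grid(0:max_age, years)
  objf <- make_objective_split(o, grid, config, population)
  start <- start_values(o, objf, config)
  lb <- c(rep(config$log_bounds$p0[1], objf$n_p0),
          rep(config$log_bounds$chi[1], objf$Ka * objf$Kt))
  ub <- c(rep(config$log_bounds$p0[2], objf$n_p0),
          rep(config$log_bounds$chi[2], objf$Ka * objf$Kt))
  opt <- stats::optim(
    start, objf$fn, objf$gr, method = "L-BFGS-B",
    lower = lb, upper = ub,
    control = list(maxit = config$maxit, pgtol = config$grad_tol, factr = 1e7)
  )
  e <- objf$forward(opt$par)
  bp <- exp(e$lbp_years)
  res <- objf$obs
  res$predicted <- e$pred
  res$residual_log <- e$r
  res$mu_log <- e$mm$m
  res$s2 <- e$mm$s2
  list(
    grid = grid,
    prevalence = prevalence_surface(grid, e$p, bp),
    chi = rate_surface(grid, e$chi),
    theta = opt$par,
    birth_prevalence = bp,
    objective = e$value,
    loglik = -e$nll,
    penalty = e$pen,
    converged = opt$convergence == 0L,
    convergence_code = opt$convergence,
    message = opt$message,
    iterations = opt$counts,
    residuals = res,
    objf = objf
  )
}

# Deterministic start: birth prevalence at the crude survey prevalence, and
# the hazard at the empirical age profile of crude CSMR / p0 (flat in
# calendar time). An age-flat hazard start would put the steep infant cells
# in a collapsed basin of the offset log-normal objective (predictions far
# below observations get vanishing pull once the prediction-based variance
# shrinks), so the start must carry the age shape of the data.
start_values <- function(o, objf, config) {
  prev <- o$value[o$measure == "prevalence"]
  p0_start <- max(stats::median(prev[prev > 0], na.rm = TRUE), 1e-5)
  if (!is.finite(p0_start)) p0_start <- 1e-3
  cs <- o[o$measure == "csmr", ]
  mid <- (cs$age_lo + cs$age_hi) / 2
  prof <- stats::aggregate(cs$value, list(age = round(mid)), mean)
  chi_age <- stats::approx(prof$age, pmax(prof$x, 1e-9), xout = objf$age_knots,
                           rule = 2)$y / p0_start
  chi_age <- pmin(pmax(chi_age, 1e-5), 2)
  c(rep(log(p0_start), objf$n_p0),
    as.vector(matrix(log(chi_age), objf$Ka, objf$Kt)))
}

#' @export
print.chd_fit <- function(x, ...) {
  for (s in names(x$sexes)) {
    f <- x$sexes[[s]]
    cat(sprintf(
      "%s: birth prevalence %.3g per 1,000%s, objective %.2f (loglik %.2f, penalty %.2f)%s\n",
      s, 1000 * f$birth_prevalence[length(f$birth_prevalence)],
      if (x$config$constant_birth_prevalence) "" else " (final year)",
      f$objective, f$loglik, f$penalty,
      if (f$converged) "" else " [NOT CONVERGED]"
    ))
  }
  invisible(x)
}
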