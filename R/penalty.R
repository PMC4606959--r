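#' @importFrom Matrix sparseMatrix crossprod t
NULL

# Sparse second-difference operators on a column-major vectorised ages x years
# grid. Directions:
#   age:    x[a-1,t] - 2 x[a,t] + x[a+1,t]           (interior ages, all years)
#   cohort: x[a,t] - 2 x[a+1,t+1] + x[a+2,t+2]       (along characteristics)
#   cross:  x[a,t] - x[a+1,t] - x[a,t+1] + x[a+1,t+1] (mixed age x year)
# Each returns a (#rows x nA*nT) sparse matrix.
second_diff_ops <- function(nA, nT) {
  idx <- function(a, t) a + (t - 1L) * nA

  at <- expand.grid(a = seq(2L, nA - 1L), t = seq_len(nT))
  n1 <- nrow(at)
  D_age <- Matrix::sparseMatrix(
    i = rep(seq_len(n1), 3L),
    j = c(idx(at$a - 1L, at$t), idx(at$a, at$t), idx(at$a + 1L, at$t)),
    x = rep(c(1, -2, 1), each = n1),
    dims = c(n1, nA * nT)
  )

  D_cohort <- NULL
  if (nA >= 3L && nT >= 3L) {
    at <- expand.grid(a = seq_len(nA - 2L), t = seq_len(nT - 2L))
    n2 <- nrow(at)
    D_cohort <- Matrix::sparseMatrix(
      i = rep(seq_len(n2), 3L),
      j = c(idx(at$a, at$t), idx(at$a + 1L, at$t + 1L), idx(at$a + 2L, at$t + 2L)),
      x = rep(c(1, -2, 1), each = n2),
      dims = c(n2, nA * nT)
    )
  }

  at <- expand.grid(a = seq_len(nA - 1L), t = seq_len(nT - 1L))
  n3 <- nrow(at)
  D_cross <- Matrix::sparseMatrix(
    i = rep(seq_len(n3), 4L),
    j = c(idx(at$a, at$t), idx(at$a + 1L, at$t),
          idx(at$a, at$t + 1L), idx(at$a + 1L, at$t + 1L)),
    x = rep(c(1, -1, -1, 1), each = n3),
    dims = c(n3, nA * nT)
  )

  list(age = D_age, cohort = D_cohort, cross = D_cross)
}

# Precision-like matrix P = sum_d D_d' D_d for the requested directions;
# penalty = x' P x / (2 sigma^2), gradient = P x / sigma^2.
penalty_matrix <- function(nA, nT, directions = c("age", "cohort", "cross")) {
  ops <- second_diff_ops(nA, nT)
  P <- NULL
  for (d in directions) {
    D <- ops[[d]]
    if (is.null(D)) next
    DtD <- Matrix::crossprod(D)
    P <- if (is.null(P)) DtD else P + DtD
  }
  P
}

#' Second-order smoothing penalty of a surface
#'
#' Sum over the penalized directions (age, cohort characteristic, and the
#' mixed age-by-year cross term) of squared second-order finite differences of
#' the log-scale surface, divided by `2 sigma^2`. The penalty is zero exactly
#' when the log surface is affine in every penalized direction; it shrinks
#' fitted surfaces toward locally log-linear behaviour across ages and
#' cohorts. The "cross-smoothing" term is the mixed second difference
#' `x[a,t] - x[a+1,t] - x[a,t+1] + x[a+1,t+1]`, which vanishes for any
#' additively separable log surface.
#'
#' @param surface a [rate_surface()] or [prevalence_surface()]; zero
#'   prevalences are floored at a tiny positive value before taking logs.
#' @param sigma smoothing scale on the log-difference scale (default 1).
#' @param directions subset of `c("age", "cohort", "cross")`.
#' @return the scalar penalty, with a `"components"` attribute holding the
#'   per-direction contributions.
#' @export
smoothing_penalty <- function(surface, sigma = 1,
                              directions = c("age", "cohort", "cross")) {
  if (sigma <= 0) stop("`sigma` must be positive")
  directions <- match.arg(directions, several.ok = TRUE)
  v <- surface$values
  nA <- nrow(v)
  nT <- ncol(v)
  if (nA < 3L) stop("grid must have at least 3 age nodes")
  x <- as.vector(log(pmax(v, .Machine$double.xmin)))
  ops <- second_diff_ops(nA, nT)
  comp <- vapply(directions, function(d) {
    D <- ops[[d]]
    if (is.null(D)) return(0)
    sum(as.vector(D %*% x)^2) / (2 * sigma^2)
  }, numeric(1))
  structure(sum(comp), components = comp)
}
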