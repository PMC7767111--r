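#' Build a clamped knot vector by knot averages
#'
#' The domain is `[t_min, t_max]` (default `[0.0025, 1]`, the support of
#' a 400-sample normalized beat on the grid `t_j = j/400`).  The first
#' and last `p + 1` knots sit at the domain endpoints; each interior knot
#' `zeta_k` (for `p+1 <= k <= m-p-1`, with `m = n+p+1`) is the average of
#' `p` consecutive terms `tau_{k+1} .. tau_{k+p}` of the arithmetic
#' sequence `tau_{p+1} .. tau_m` running from `t_min` to `t_max`.
#'
#' @param n highest coefficient index: the spline has `n + 1` basis
#'   functions (default 15, i.e. 16 coefficients per lead).
#' @param p spline degree (default 3, cubic).
#' @param t_min,t_max domain endpoints.
#' @return an object of class `knot_vector`: list with `knots`
#'   (`zeta_0 .. zeta_m`, length `m + 1`), `p`, `n`, `m`.
#' @export
build_knots <- function(n = 15L, p = 3L, t_min = 0.0025, t_max = 1) {
  n <- as.integer(n); p <- as.integer(p)
  if (p < 1L) stop("degree p must be >= 1")
  if (n < p + 1L) stop("n must be at least p + 1 (got n = ", n, ", p = ", p, ")")
  m <- n + p + 1L
  tau <- seq(t_min, t_max, length.out = m - p)  # tau_{p+1} .. tau_m
  knots <- numeric(m + 1L)                      # zeta_0 .. zeta_m (1-based + 1)
  knots[1:(p + 1L)] <- t_min
  knots[(m - p + 1L):(m + 1L)] <- t_max
  for (k in (p + 1L):(m - p - 1L)) {
    # tau_{k+1} .. tau_{k+p}  ->  tau[(k+1-p) : k]
    knots[k + 1L] <- mean(tau[(k + 1L - p):k])
  }
  structure(list(knots = knots, p = p, n = n, m = m,
                 t_min = t_min, t_max = t_max),
            class = "knot_vector")
}

#' Evaluate one B-spline basis function (Cox-de Boor recursion)
#'
#' Degree-0 functions are indicators of the half-open knot spans
#' `[zeta_i, zeta_{i+1})`; higher degrees follow the standard two-term
#' recursion with the `0/0 = 0` convention.  At the right domain
#' endpoint the last span is treated as closed so the basis still sums
#' to one.
#'
#' @param t evaluation point(s) in `[t_min, t_max]`.
#' @param i basis index, `0 <= i <= n`.
#' @param p degree (defaults to the knot vector's).
#' @param knots a [build_knots()] object.
#' @return numeric value(s) in `[0, 1]`.
#' @export
bspline_basis <- function(t, i, p = knots$p, knots) {
  if (i < 0L || i > knots$m - p - 1L)
    stop("basis index i = ", i, " out of range [0, ", knots$m - p - 1L, "]")
  kv <- knots$knots
  tmax <- knots$t_max
  rec <- function(tt, ii, pp) {
    if (pp == 0L) {
      inside <- (kv[ii + 1L] <= tt & tt < kv[ii + 2L]) |
        (tt == tmax & kv[ii + 2L] == tmax & kv[ii + 1L] < tmax)
      return(as.numeric(inside))
    }
    d1 <- kv[ii + pp + 1L] - kv[ii + 1L]
    d2 <- kv[ii + pp + 2L] - kv[ii + 2L]
    a <- if (d1 > 0) (tt - kv[ii + 1L]) / d1 * rec(tt, ii, pp - 1L) else 0
    b <- if (d2 > 0) (kv[ii + pp + 2L] - tt) / d2 * rec(tt, ii + 1L, pp - 1L) else 0
    a + b
  }
  rec(t, as.integer(i), as.integer(p))
}

#' B-spline design matrix on a grid
#'
#' @param t evaluation points.
#' @param knots a [build_knots()] object.
#' @return `length(t)` x `(n + 1)` matrix with entry `(j, i+1) =
#'   B_{i,p}(t_j)`.
#' @export
bspline_design <- function(t, knots) {
  n1 <- knots$n + 1L
  B <- vapply(0:(n1 - 1L), function(i) bspline_basis(t, i, knots$p, knots),
              numeric(length(t)))
  matrix(B, nrow = length(t), ncol = n1)
}

#' Least-squares B-spline fit of a normalized beat
#'
#' Coefficients minimize the sum of squared residuals of
#' `u(t) = sum_i a_i B_{i,p}(t)` over the beat's grid, solved by QR
#' decomposition for numerical robustness.
#'
#' @param samples numeric vector, the normalized beat (length `N >= n+1`).
#' @param knots a [build_knots()] object.
#' @param t evaluation grid; default `j / N` for `j = 1..N`, which for
#'   `N = 400` spans exactly the knot domain `[0.0025, 1]`.
#' @return an object of class `spline_fit`: list with `coefficients`
#'   (`a_0 .. a_n`), `residual` (sum of squared residuals), `n`, `knots`,
#'   `t`.
#' @export
fit_spline <- function(samples, knots = build_knots(), t = NULL) {
  N <- length(samples)
  if (N < knots$n + 1L)
    stop("beat has ", N, " samples but the spline needs at least ",
         knots$n + 1L)
  if (is.null(t)) t <- seq_len(N) / N
  B <- bspline_design(t, knots)
  qrB <- qr(B)
  if (qrB$rank < ncol(B))
    stop("rank-deficient spline design (rank ", qrB$rank, " < ", ncol(B),
         "); check knot placement against the evaluation grid")
  a <- qr.coef(qrB, samples)
  res <- sum((samples - B %*% a)^2)
  structure(list(coefficients = as.numeric(a), residual = res,
                 n = knots$n, knots = knots, t = t),
            class = "spline_fit")
}

#' Evaluate a fitted spline
#' @param fit a `spline_fit`.
#' @param t evaluation points (defaults to the fitting grid).
#' @return numeric vector `u(t)`.
#' @export
spline_eval <- function(fit, t = fit$t) {
  as.numeric(bspline_design(t, fit$knots) %*% fit$coefficients)
}

#' Assemble the 52-dimensional per-heartbeat feature vector
#'
#' Order: the `n + 1` coefficients of the Vx fit, then Vy, then Vz
#' (48 values for `n = 15`), then the time scaling factor `alpha`, then
#' the three per-lead amplitude factors `beta`.
#'
#' @param fits list of three `spline_fit` objects (leads x, y, z), all
#'   with the same coefficient count.
#' @param alpha time scaling factor.
#' @param beta numeric length-3 amplitude scaling factors.
#' @return named numeric vector (`ax0..ax15, ay0.., az0.., alpha,
#'   beta_x, beta_y, beta_z` for `n = 15`).
#' @export
assemble_features <- function(fits, alpha, beta) {
  if (length(fits) != 3L) stop("need exactly 3 spline fits (leads x, y, z)")
  nc <- vapply(fits, function(f) length(f$coefficients), integer(1L))
  if (length(unique(nc)) != 1L)
    stop("coefficient count mismatch across leads: ",
         paste(nc, collapse = ", "))
  if (length(beta) != 3L) stop("beta must have 3 values")
  axes <- c("x", "y", "z")
  coefs <- unlist(lapply(1:3, function(j) {
    v <- fits[[j]]$coefficients
    names(v) <- paste0("a", axes[j], seq_along(v) - 1L)
    v
  }))
  c(coefs, alpha = alpha,
    stats::setNames(beta, paste0("beta_", axes)))
}

#' Spline feature vector for one normalized beat over a lead subset
#'
#' For each requested lead: `n + 1` spline coefficients; then `alpha`,
#' then that subset's `beta` factors.  With the three Frank leads and
#' `n = 15` this is the canonical 52-dimensional vector; a single lead
#' gives 16 + 1 + 1 = 18 features.
#'
#' @param beat one normalized beat from [normalize_beats()].
#' @param knots a [build_knots()] object.
#' @param leads leads to include, in order (default: all in the beat).
#' @return named numeric feature vector.
#' @export
beat_features <- function(beat, knots = build_knots(),
                          leads = names(beat$leads)) {
  stopifnot(all(leads %in% names(beat$leads)))
  coefs <- unlist(lapply(leads, function(l) {
    f <- fit_spline(beat$leads[[l]]$samples, knots)
    stats::setNames(f$coefficients,
                    paste0("a_", l, "_", seq_along(f$coefficients) - 1L))
  }))
  betas <- vapply(leads, function(l) beat$leads[[l]]$beta, numeric(1L))
  c(coefs, alpha = beat$alpha,
    stats::setNames(betas, paste0("beta_", leads)))
}
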