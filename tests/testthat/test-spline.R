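# one plausible "random smooth beat" on the 400-point grid
smooth_beat <- function(seed) {
  set.seed(seed)
  t <- (1:400) / 400
  y <- rowSums(vapply(1:4, function(k)
    stats::rnorm(1) * sin(2 * pi * k * t + stats::runif(1, 0, 2 * pi)),
    numeric(400L)))
  (y - min(y)) / (max(y) - min(y))
}

test_that("knot construction matches the arithmetic knot-average rule", {
  kn <- build_knots(n = 15L, p = 3L)
  expect_identical(kn$m, 19L)
  expect_length(kn$knots, 20L)
  d <- (1 - 0.0025) / 15
  expect_equal(kn$knots[4 + 1], 0.0025 + 2 * d, tolerance = 1e-12)   # zeta_4
  expect_equal(kn$knots[15 + 1], 0.0025 + 13 * d, tolerance = 1e-12) # zeta_15
  expect_true(all(kn$knots[1:4] == 0.0025))
  expect_true(all(kn$knots[17:20] == 1))

  for (n in c(7L, 11L, 15L, 23L)) {
    k <- build_knots(n, 3L)
    expect_true(all(diff(k$knots) >= 0))
    inner <- k$knots[(k$p + 2L):(k$m - k$p)]
    expect_true(all(inner > 0.0025 & inner < 1))
  }
  expect_error(build_knots(3L, 3L), "at least p \\+ 1")
})

test_that("degree-0 basis is the span indicator; index range enforced", {
  kn <- build_knots(8L, 3L)
  z <- kn$knots
  i <- 5L
  mid <- (z[i + 1] + z[i + 2]) / 2
  expect_identical(bspline_basis(mid, i, 0L, kn), 1)
  expect_identical(bspline_basis(z[i + 2] + 1e-9, i, 0L, kn), 0)
  expect_error(bspline_basis(0.5, 99L, knots = kn), "out of range")
})

test_that("partition of unity, local support, clamped endpoint interpolation", {
  kn <- build_knots(15L, 3L)
  set.seed(2)
  t <- c(0.0025, 1, stats::runif(100, 0.0025, 1))
  B <- bspline_design(t, kn)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
  expect_true(all(B >= 0 & B <= 1 + 1e-12))
  expect_identical(bspline_basis(0.0025, 0L, knots = kn), 1)
  expect_identical(bspline_basis(1, 15L, knots = kn), 1)
  # local support: zero outside [zeta_i, zeta_{i+p+1}]
  z <- kn$knots
  for (i in c(3L, 9L)) {
    expect_identical(bspline_basis(z[i + 1] - 1e-6, i, knots = kn), 0)
    expect_identical(bspline_basis(z[i + 3 + 2] + 1e-6, i, knots = kn), 0)
  }
})

test_that("basis agrees with the independent splineDesign evaluation", {
  for (n in c(7L, 15L, 23L)) {
    kn <- build_knots(n, 3L)
    t <- (1:400) / 400
    B <- bspline_design(t, kn)
    B_ref <- splines::splineDesign(kn$knots, t, ord = 4L, outer.ok = TRUE)
    expect_lt(max(abs(B - B_ref)), 1e-12)
  }
})

test_that("constant and cubic-polynomial beats are reproduced exactly", {
  kn <- build_knots(15L, 3L)
  fit_c <- fit_spline(rep(0.42, 400), kn)
  expect_lt(max(abs(fit_c$coefficients - 0.42)), 1e-9)

  t <- (1:400) / 400
  poly <- 0.3 - 0.8 * t + 1.9 * t^2 - 1.1 * t^3
  fit_p <- fit_spline(poly, kn)
  expect_lt(fit_p$residual, 1e-16 * 400)
})

test_that("fit agrees with a dense normal-equations oracle on random beats", {
  kn <- build_knots(15L, 3L)
  t <- (1:400) / 400
  B_ref <- splines::splineDesign(kn$knots, t, ord = 4L, outer.ok = TRUE)
  worst <- 0
  for (s in 1:100) {
    y <- smooth_beat(s)
    a_oracle <- solve(crossprod(B_ref), crossprod(B_ref, y))
    fit <- fit_spline(y, kn)
    worst <- max(worst, max(abs(fit$coefficients - a_oracle)))
  }
  expect_lt(worst, 1e-8)
})

test_that("residual is monotone non-increasing in n; fit is idempotent", {
  y <- smooth_beat(99)
  res <- vapply(c(7L, 11L, 15L, 23L), function(n)
    fit_spline(y, build_knots(n, 3L))$residual, numeric(1L))
  expect_true(all(diff(res) <= 1e-12))

  kn <- build_knots(15L, 3L)
  fit <- fit_spline(y, kn)
  regen <- spline_eval(fit)
  refit <- fit_spline(regen, kn)
  expect_lt(max(abs(refit$coefficients - fit$coefficients)), 1e-10)
})

test_that("assemble_features: 52 values, order-sensitive, zero passthrough", {
  kn <- build_knots(15L, 3L)
  fits <- lapply(1:3, function(s) fit_spline(smooth_beat(s), kn))
  fv <- assemble_features(fits, alpha = 0.9, beta = c(1.1, 0.8, 0.6))
  expect_length(fv, 52L)
  expect_identical(unname(fv[49]), 0.9)
  fv_perm <- assemble_features(fits[c(2, 1, 3)], 0.9, c(1.1, 0.8, 0.6))
  expect_false(isTRUE(all.equal(unname(fv), unname(fv_perm))))

  zero_fit <- fit_spline(rep(0, 400), kn)
  fz <- assemble_features(list(zero_fit, zero_fit, zero_fit), 0, c(0, 0, 0))
  expect_identical(unname(fz), rep(0, 52L))
  expect_error(assemble_features(fits[1:2], 1, c(1, 1, 1)), "exactly 3")
})
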