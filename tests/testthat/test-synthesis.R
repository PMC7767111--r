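test_that("build_windows enumerates stride-1 right-aligned pairs", {
  x <- 1:10
  Y <- cbind(10 * x, 20 * x, 30 * x)
  ws <- build_windows(x, Y, L = 3L)
  expect_identical(ws$n_windows, 8L)
  first <- window_pair(ws, 1L)
  expect_identical(first$s, c(1, 2, 3))
  expect_identical(first$y, c(30, 60, 90))
  last <- window_pair(ws, 8L)
  expect_identical(last$s, c(8, 9, 10))

  expect_identical(build_windows(x, Y, L = 1L)$n_windows, 10L)
  expect_identical(window_pair(build_windows(x, Y, L = 1L), 4L)$s, 4)
  expect_identical(build_windows(x, Y, L = 10L)$n_windows, 1L)
  expect_error(build_windows(x, Y, L = 11L), "shorter than the window")
})

test_that("lstm_step fixed points and gate saturation", {
  H <- 3L
  zeros <- rand_layer(H, 2L)
  for (nm in names(zeros)) zeros[[nm]][] <- 0
  st <- lstm_step(zeros, c(1.3, -0.2), rep(0, H), rep(0, H))
  expect_identical(st$h, rep(0, H))
  expect_identical(st$c, rep(0, H))

  sat <- zeros
  sat$bf[] <- 20   # forget gate ~ 1
  sat$bi[] <- -20  # input gate ~ 0
  st <- lstm_step(sat, c(0.5, -0.4), rep(0, H), rep(0.7, H))
  expect_equal(st$c, rep(0.7, H), tolerance = 1e-6)
})

test_that("lstm_step matches a hand scalar evaluation (all weights 0.5)", {
  p <- rand_layer(1L, 1L)
  for (nm in c("Wf", "Wi", "Wc", "Wo", "Uf", "Ui", "Uc", "Uo"))
    p[[nm]][] <- 0.5
  for (nm in c("bf", "bi", "bc", "bo")) p[[nm]][] <- 0
  # independent scalar evaluation, written out gate by gate
  sg <- function(z) 1 / (1 + exp(-z))
  f <- sg(0.5 * 1); i <- sg(0.5 * 1); cb <- tanh(0.5 * 1); o <- sg(0.5 * 1)
  c_exp <- f * 0 + i * cb
  h_exp <- o * tanh(c_exp)
  st <- lstm_step(p, 1, 0, 0)
  expect_equal(st$c, c_exp, tolerance = 1e-12)
  expect_equal(st$h, h_exp, tolerance = 1e-12)
})

test_that("compiled batched forward agrees with the scalar-loop oracle", {
  set.seed(31)
  for (rep in 1:3) {
    H <- sample(1:3, 1)
    L <- 5L
    layers <- list(rand_layer(H, 1L), rand_layer(H, H))
    Wout <- matrix(rnorm(3 * H), 3, H)
    bout <- rnorm(3)
    x <- rnorm(20)
    ends <- c(5L, 11L, 20L)
    got <- vcgmi:::cpp_lstm_forward(layers, Wout, bout, x, ends, L)
    want <- lstm_oracle_predict(layers, Wout, bout, x, ends, L)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("analytic BPTT gradients match numerical differentiation", {
  set.seed(13)
  H <- 2L; L <- 4L
  layers <- list(rand_layer(H, 1L), rand_layer(H, H))
  Wout <- matrix(rnorm(3 * H), 3, H)
  bout <- rnorm(3)
  x <- rnorm(10)
  ends <- c(4L, 7L, 10L)
  Y <- matrix(rnorm(9), 3, 3)
  loss_fn <- function(layers, Wout, bout)
    vcgmi:::cpp_lstm_loss_grad(layers, Wout, bout, x, Y, ends, L)$loss
  gr <- vcgmi:::cpp_lstm_loss_grad(layers, Wout, bout, x, Y, ends, L)
  eps <- 1e-6
  worst <- 0
  for (l in 1:2) for (nm in names(layers[[l]])) {
    for (k in seq_along(layers[[l]][[nm]])) {
      up <- layers; up[[l]][[nm]][k] <- up[[l]][[nm]][k] + eps
      dn <- layers; dn[[l]][[nm]][k] <- dn[[l]][[nm]][k] - eps
      g_num <- (loss_fn(up, Wout, bout) - loss_fn(dn, Wout, bout)) / (2 * eps)
      g_an <- gr$layers[[l]][[nm]][k]
      worst <- max(worst, abs(g_num - g_an) /
                            max(1e-8, abs(g_num) + abs(g_an)))
    }
  }
  for (k in seq_along(Wout)) {
    up <- Wout; up[k] <- up[k] + eps
    dn <- Wout; dn[k] <- dn[k] - eps
    g_num <- (loss_fn(layers, up, bout) - loss_fn(layers, dn, bout)) / (2 * eps)
    worst <- max(worst, abs(g_num - gr$Wout[k]) /
                          max(1e-8, abs(g_num) + abs(gr$Wout[k])))
  }
  expect_lt(worst, 1e-4)
})

test_that("rmse matches direct evaluation", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3), tolerance = 1e-12)
  v <- rnorm(50)
  expect_equal(rmse(v, v + 0.37), 0.37, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("cc is the uncentered cosine: scale-invariant, not shift-invariant", {
  v <- c(1, 2, 3, 4)
  expect_equal(cc(v, 2 * v), 1, tolerance = 1e-12)
  expect_equal(cc(c(1, 0), c(0, 1)), 0, tolerance = 1e-12)
  expect_equal(cc(c(1, 1), c(1, -1)), 0, tolerance = 1e-12)
  set.seed(4)
  w <- rnorm(30)
  expect_equal(cc(v + 0, 0.01 * v), 1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cc(w, w), cc(w, w + 5))))
  expect_error(cc(c(0, 0), c(1, 2)), "all-zero")
})

test_that("derive_vcg shape contract, determinism, stride consistency", {
  set.seed(21)
  model <- structure(list(
    layers = list(rand_layer(4L, 1L, sd = 0.3), rand_layer(4L, 4L, sd = 0.3)),
    Wout = matrix(rnorm(12, 0, 0.3), 3, 4), bout = rep(0, 3),
    L = 10L, sampling_rate = 500,
    x_center = 0, x_scale = 1, y_center = rep(0, 3), y_scale = rep(1, 3)),
    class = "vcg_synthesizer")
  x <- rnorm(60)
  out <- derive_vcg(model, x)
  expect_identical(nrow(out$signals), length(x) - 10L + 1L)
  expect_identical(lead_names(out), c("vx_hat", "vy_hat", "vz_hat"))
  expect_true(all(is.finite(out$signals)))
  expect_identical(out$signals, derive_vcg(model, x)$signals)
  # shifting the input by k shifts the output by k
  k <- 7L
  out2 <- derive_vcg(model, x[(k + 1):length(x)])
  expect_equal(out2$signals,
               out$signals[(k + 1):nrow(out$signals), ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(derive_vcg(model, rnorm(5)), "shorter than the window")
})

test_that("constant targets are recovered and training is seed-deterministic", {
  rec <- clean_record(6, mean_rr = 0.75, seed = 17)
  const <- multi_lead_record(
    cbind(i = get_lead(rec, "i"),
          vx = rep(0.3, 3000), vy = rep(0.3, 3000), vz = rep(0.3, 3000)),
    500)
  cfg <- synth_config(L = 20L, hidden = 8L, epochs = 20L, batch_size = 128L,
                      max_train_windows = 1500L, seed = 2L)
  m <- train_synthesizer(const, cfg)
  pred <- derive_vcg(m, get_lead(rec, "i"))
  expect_lt(rmse(rep(0.3, nrow(pred$signals)), get_lead(pred, "vx_hat")), 0.01)
  expect_lt(rmse(rep(0.3, nrow(pred$signals)), get_lead(pred, "vz_hat")), 0.01)
  # determinism
  cfg2 <- synth_config(L = 20L, hidden = 4L, epochs = 2L,
                       max_train_windows = 300L, seed = 9L)
  m1 <- train_synthesizer(rec, cfg2)
  m2 <- train_synthesizer(rec, cfg2)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$Wout, m2$Wout)
  # loss history decreases on average
  expect_lt(mean(utils::tail(m$loss_history, 5)),
            mean(utils::head(m$loss_history, 5)))
  expect_error(train_synthesizer(const, synth_config(L = 2000L)),
               "too short")
})

test_that("feedforward baseline recovers constants and a linear mixing", {
  rec <- clean_record(8, mean_rr = 0.75, seed = 23)
  n <- nrow(rec$signals)
  const <- multi_lead_record(
    cbind(i = get_lead(rec, "i"), vx = rep(0.3, n), vy = rep(0.3, n),
          vz = rep(0.3, n)), 500)
  cfg <- synth_config(L = 20L, hidden = 30L, epochs = 100L,
                      learning_rate = 3e-3, max_train_windows = 2000L,
                      seed = 3L)
  m <- baseline_mlp_synthesizer(const, cfg)
  pred <- derive_vcg(m, get_lead(rec, "i"))
  expect_lt(rmse(rep(0.3, nrow(pred$signals)), get_lead(pred, "vy_hat")), 0.01)

  mix <- recovery_mixing()
  mrec <- linear_mixing_record(rec, mix)
  nm <- nrow(mrec$signals)
  tr <- multi_lead_record(mrec$signals[1:round(0.75 * nm), ], 500)
  te <- multi_lead_record(mrec$signals[(round(0.75 * nm) + 1):nm, ], 500)
  cfg2 <- synth_config(L = 40L, hidden = 60L, epochs = 60L,
                       learning_rate = 2e-3, max_train_windows = 2500L,
                       seed = 4L)
  m2 <- baseline_mlp_synthesizer(tr, cfg2)
  fid <- fidelity_report(te, derive_vcg(m2, get_lead(te, "i")))
  expect_true(all(fid$cc > 0.9))
  # seeded determinism
  cfg3 <- synth_config(L = 20L, hidden = 10L, epochs = 2L,
                       max_train_windows = 300L, seed = 8L)
  expect_identical(baseline_mlp_synthesizer(rec, cfg3)$net$W,
                   baseline_mlp_synthesizer(rec, cfg3)$net$W)
})
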