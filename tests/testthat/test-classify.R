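make_gaussians <- function(n_per, d = 52L, k = 3L, sep = 5, seed = 1) {
  set.seed(seed)
  mu <- matrix(0, k, d)
  for (j in seq_len(k)) mu[j, j] <- sep  # means 5 sigma apart (unit noise)
  X <- do.call(rbind, lapply(seq_len(k), function(j)
    sweep(matrix(stats::rnorm(n_per * d), n_per, d), 2L, mu[j, ], "+")))
  list(X = X, y = rep(mi_classes()[seq_len(k)], each = n_per))
}

test_that("SMOTE: balanced input returned unchanged; target counts reached", {
  set.seed(5)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c("AMI", "IMI", "HC"), each = 20)
  out <- smote_oversample(X, y)
  expect_identical(out$X, X)
  expect_identical(out$y, y)

  X2 <- matrix(rnorm(110 * 4), 110, 4)
  y2 <- rep(c("HC", "AMI"), c(100, 10))
  out2 <- smote_oversample(X2, y2, k = 5, seed = 3)
  expect_identical(as.integer(table(out2$y)[c("HC", "AMI")]), c(100L, 100L))
})

test_that("SMOTE originals are untouched; synthetic points lie on kNN segments", {
  set.seed(8)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c("HC", "IMI"), c(30, 10))
  out <- smote_oversample(X, y, k = 4, seed = 11)
  expect_identical(out$X[1:40, ], X)
  syn <- out$X[41:nrow(out$X), , drop = FALSE]
  Xm <- X[y == "IMI", ]
  # brute-force: each synthetic point must lie on a segment between some
  # minority point and one of its 4 nearest minority neighbors
  d2 <- as.matrix(dist(Xm))^2; diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[1:4]))
  on_segment <- function(s) {
    for (a in seq_len(nrow(Xm))) for (b in nn[a, ]) {
      ab <- Xm[b, ] - Xm[a, ]
      u <- sum((s - Xm[a, ]) * ab) / sum(ab^2)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((Xm[a, ] + u * ab - s)^2)) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))
})

test_that("SMOTE edge policies: singleton class errors, small class lowers k", {
  X <- matrix(rnorm(22 * 2), 22, 2)
  y <- rep(c("HC", "AMI"), c(21, 1))
  expect_error(smote_oversample(X, y), "single member")
  y2 <- rep(c("HC", "AMI"), c(18, 4))
  expect_message(smote_oversample(X, y2, k = 5), "using k = 3")
})

test_that("classifier: softmax rows, separable accuracy, determinism", {
  g <- make_gaussians(200L)
  idx <- sample(rep(c(TRUE, FALSE), c(150, 50) * 3))
  cfg <- clf_config(hidden = c(64L, 32L), epochs = 120L,
                    learning_rate = 3e-3, seed = 6L)
  model <- train_classifier(g$X[idx, ], g$y[idx], cfg)
  pr <- predict(model, g$X[!idx, ])
  expect_equal(unname(rowSums(pr$prob)), rep(1, sum(!idx)), tolerance = 1e-9)
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  expect_gte(mean(pr$class == g$y[!idx]), 0.99)

  model2 <- train_classifier(g$X[idx, ], g$y[idx], cfg)
  expect_identical(model$net$W, model2$net$W)
})

test_that("prediction: tie-break to lowest index, row-wise independence", {
  # hand-built model with all-zero weights -> uniform softmax everywhere
  g <- make_gaussians(30L, d = 4L)
  cfg <- clf_config(hidden = c(5L), epochs = 1L, seed = 1L)
  model <- train_classifier(g$X, g$y, cfg)
  for (l in seq_along(model$net$W)) {
    model$net$W[[l]][] <- 0
    model$net$b[[l]][] <- 0
  }
  pr <- predict(model, g$X[1:3, ])
  expect_equal(unname(pr$prob[1, ]), rep(1 / 12, 12), tolerance = 1e-12)
  expect_identical(pr$index, rep(1L, 3L))
  expect_identical(pr$class, rep(mi_classes()[1L], 3L))

  model_t <- train_classifier(g$X, g$y, clf_config(hidden = c(8L),
                                                   epochs = 20L, seed = 2L))
  single <- predict(model_t, g$X[5, , drop = FALSE])
  dup <- predict(model_t, g$X[c(5, 5, 7), ])
  expect_equal(unname(dup$prob[1, ]), unname(single$prob[1, ]),
               tolerance = 1e-12)
  expect_equal(unname(dup$prob[2, ]), unname(single$prob[1, ]),
               tolerance = 1e-12)
  expect_error(predict(model_t, g$X[, 1:3]), "feature width")
})

test_that("softmax/cross-entropy backward pass matches numerical gradients", {
  set.seed(44)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- sample(1:3, 12, replace = TRUE)
  Y <- matrix(0, 12, 3); Y[cbind(1:12, y)] <- 1
  net <- vcgmi:::dense_net_init(c(4L, 6L, 3L), seed = 1)
  net$output <- "softmax"; net$loss <- "cross_entropy"
  gr <- vcgmi:::dense_net_grad(net, X, Y)
  loss_at <- function(net) {
    fw <- vcgmi:::dense_net_forward(net, X)
    vcgmi:::dense_net_loss(net, fw$output, Y)
  }
  eps <- 1e-6
  worst <- 0
  for (l in 1:2) {
    for (k in seq_along(net$W[[l]])) {
      up <- net; up$W[[l]][k] <- up$W[[l]][k] + eps
      dn <- net; dn$W[[l]][k] <- dn$W[[l]][k] - eps
      g_num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      worst <- max(worst, abs(g_num - gr$W[[l]][k]) /
                            max(1e-8, abs(g_num) + abs(gr$W[[l]][k])))
    }
    for (k in seq_along(net$b[[l]])) {
      up <- net; up$b[[l]][k] <- up$b[[l]][k] + eps
      dn <- net; dn$b[[l]][k] <- dn$b[[l]][k] - eps
      g_num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      worst <- max(worst, abs(g_num - gr$b[[l]][k]) /
                            max(1e-8, abs(g_num) + abs(gr$b[[l]][k])))
    }
  }
  expect_lt(worst, 1e-4)
})
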