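# Shared fully connected network engine: ReLU hidden layers, identity or
# softmax output, MSE or cross-entropy loss, Adam, mini-batches, optional
# early stopping on a validation split.  Used by the feedforward VCG
# baseline (identity/MSE) and the beat classifier (softmax/CE).

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

dense_net_init <- function(sizes, seed) {
  # He initialization for the ReLU stack
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l + 1L] * sizes[l], 0,
                                  sqrt(2 / sizes[l])),
                     sizes[l + 1L], sizes[l])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

dense_net_forward <- function(net, X) {
  nl <- length(net$W)
  A <- list(X)
  Z <- vector("list", nl)
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(A[[l]] %*% t(net$W[[l]]), 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < nl) relu(Z[[l]]) else switch(net$output,
      identity = Z[[l]], softmax = softmax_rows(Z[[l]]))
  }
  list(output = A[[nl + 1L]], A = A, Z = Z)
}

dense_net_loss <- function(net, out, Y) {
  switch(net$loss,
    mse = mean((out - Y)^2),
    cross_entropy = -mean(rowSums(Y * log(pmax(out, 1e-300)))))
}

dense_net_grad <- function(net, X, Y) {
  fw <- dense_net_forward(net, X)
  n <- nrow(X)
  nl <- length(net$W)
  delta <- switch(net$loss,
    mse = 2 * (fw$output - Y) / (n * ncol(Y)),
    cross_entropy = (fw$output - Y) / n)  # softmax + CE combined gradient
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in nl:1) {
    gW[[l]] <- t(delta) %*% fw$A[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% net$W[[l]]) * (fw$Z[[l - 1L]] > 0)
  }
  list(loss = dense_net_loss(net, fw$output, Y), W = gW, b = gb)
}

dense_net_train <- function(X, Y, hidden, output = c("identity", "softmax"),
                            loss = c("mse", "cross_entropy"),
                            epochs = 200L, batch_size = 64L,
                            learning_rate = 1e-3, seed = 1L,
                            validation_frac = 0, patience = 20L) {
  output <- match.arg(output)
  loss <- match.arg(loss)
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  val_idx <- integer(0)
  if (validation_frac > 0 && nrow(X) >= 20L)
    val_idx <- sample.int(nrow(X), max(1L, round(validation_frac * nrow(X))))
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)

  sizes <- c(ncol(X), hidden, ncol(Y))
  net <- dense_net_init(sizes, seed)
  net$output <- output
  net$loss <- loss
  net$sizes <- sizes

  st <- adam_init(list(W = net$W, b = net$b))
  loss_hist <- numeric(0)
  best <- list(val = Inf, W = net$W, b = net$b, since = 0L)
  nb <- max(1L, ceiling(length(tr_idx) / batch_size))
  for (ep in seq_len(epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0
    for (bt in seq_len(nb)) {
      sel <- ord[seq.int((bt - 1L) * batch_size + 1L,
                         min(bt * batch_size, length(ord)))]
      gr <- dense_net_grad(net, X[sel, , drop = FALSE], Y[sel, , drop = FALSE])
      if (!is.finite(gr$loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; lower the learning rate")
      ep_loss <- ep_loss + gr$loss * length(sel)
      upd <- adam_update(list(W = net$W, b = net$b),
                         list(W = gr$W, b = gr$b), st, lr = learning_rate)
      net$W <- upd$params$W; net$b <- upd$params$b
      st <- upd$state
    }
    loss_hist <- c(loss_hist, ep_loss / length(tr_idx))
    if (length(val_idx)) {
      vout <- dense_net_forward(net, X[val_idx, , drop = FALSE])$output
      vloss <- dense_net_loss(net, vout, Y[val_idx, , drop = FALSE])
      if (vloss < best$val - 1e-9) {
        best <- list(val = vloss, W = net$W, b = net$b, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= patience) break
      }
    }
  }
  if (length(val_idx) && is.finite(best$val)) {
    net$W <- best$W; net$b <- best$b
  }
  net$loss_history <- loss_hist
  net
}
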