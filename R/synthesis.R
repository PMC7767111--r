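#' Build stride-1 sliding-window training pairs
#'
#' For a window length `L`, pair `t` (for `t = L .. T`) couples the lead-I
#' history `x[t-L+1 .. t]` with the synchronous three-lead target
#' `Y[t, ]`.
#'
#' @param x numeric lead-I sequence of length `T`.
#' @param Y `T` x 3 numeric matrix of Frank X, Y, Z targets (or `NULL`
#'   for prediction-only windows).
#' @param L window length (default 150, the empirically chosen size).
#' @return a list with `ends` (window end indices `L..T`), `L`, and
#'   accessor-friendly `x`, `Y`; `n_windows = T - L + 1`.
#' @export
build_windows <- function(x, Y = NULL, L = 150L) {
  L <- as.integer(L)
  if (L < 1L) stop("window length L must be >= 1")
  if (length(x) < L)
    stop("sequence of length ", length(x), " is shorter than the window (",
         L, ")")
  if (!is.null(Y)) {
    Y <- as.matrix(Y)
    if (nrow(Y) != length(x)) stop("x and Y must have equal length")
  }
  structure(list(x = as.numeric(x), Y = Y, L = L,
                 ends = seq.int(L, length(x)),
                 n_windows = length(x) - L + 1L),
            class = "window_set")
}

#' Extract one window pair from a window set
#' @param ws a `window_set` from [build_windows()].
#' @param j window number (1-based; window `j` ends at sample `L + j - 1`).
#' @return list with `s` (length-`L` input window) and `y` (length-3
#'   target, or `NULL`).
#' @export
window_pair <- function(ws, j) {
  t_end <- ws$ends[j]
  list(s = ws$x[(t_end - ws$L + 1L):t_end],
       y = if (is.null(ws$Y)) NULL else ws$Y[t_end, ])
}

#' One LSTM cell step (reference implementation)
#'
#' The gate equations of the memory cell: with sigmoid gates f (forget),
#' i (input), o (output) and candidate tanh activation, the cell state is
#' `c = f * c_prev + i * tanh(Wc x + Uc h_prev + bc)` and the hidden
#' state `h = o * tanh(c)`.  This pure-R version defines the contract the
#' compiled batched kernel is tested against.
#'
#' @param params list with matrices `Wf, Wi, Wc, Wo` (H x D), `Uf, Ui,
#'   Uc, Uo` (H x H) and vectors `bf, bi, bc, bo` (length H).
#' @param x_t input vector (length D).
#' @param h_prev,c_prev previous hidden and cell state (length H).
#' @return list with elements `h` and `c`.
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev) {
  sg <- function(z) 1 / (1 + exp(-z))
  chk <- function(W, d) if (ncol(W) != d)
    stop("shape mismatch: weight has ", ncol(W), " columns, input length ", d)
  chk(params$Wf, length(x_t)); chk(params$Uf, length(h_prev))
  if (length(h_prev) != length(c_prev))
    stop("h_prev and c_prev must have equal length")
  f <- sg(params$Wf %*% x_t + params$Uf %*% h_prev + params$bf)
  i <- sg(params$Wi %*% x_t + params$Ui %*% h_prev + params$bi)
  cb <- tanh(params$Wc %*% x_t + params$Uc %*% h_prev + params$bc)
  o <- sg(params$Wo %*% x_t + params$Uo %*% h_prev + params$bo)
  c_t <- as.numeric(f * c_prev + i * cb)
  h_t <- as.numeric(o * tanh(c_t))
  list(h = h_t, c = c_t)
}

init_lstm_layer <- function(hidden, input_dim) {
  sd <- 1 / sqrt(max(hidden, input_dim))
  mk <- function(r, co) matrix(stats::rnorm(r * co, 0, sd), r, co)
  list(Wf = mk(hidden, input_dim), Wi = mk(hidden, input_dim),
       Wc = mk(hidden, input_dim), Wo = mk(hidden, input_dim),
       Uf = mk(hidden, hidden), Ui = mk(hidden, hidden),
       Uc = mk(hidden, hidden), Uo = mk(hidden, hidden),
       bf = rep(1, hidden),  # forget-gate bias init at 1: standard practice
       bi = rep(0, hidden), bc = rep(0, hidden), bo = rep(0, hidden))
}

# elementwise walk over two identically shaped nested numeric lists
map2_params <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) map2_params(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

adam_init <- function(params)
  list(m = map2_params(function(a, b) a * 0, params, params),
       v = map2_params(function(a, b) a * 0, params, params),
       t = 0L)

adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
  state$v <- map2_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- map2_params(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                      state$m, state$v)
  params <- map2_params(`-`, params, step)
  list(params = params, state = state)
}

#' Training configuration for the VCG synthesizer
#'
#' @param L sliding-window length in samples (default 150, i.e. 0.3 s at
#'   500 Hz).
#' @param hidden hidden width per recurrent layer (default 30).
#' @param layers number of recurrent layers (default 2).
#' @param epochs training epochs (default 300 as in the full protocol;
#'   tests use scaled-down values).
#' @param batch_size mini-batch size (default 128).
#' @param learning_rate Adam learning rate.
#' @param max_train_windows cap on the number of stride-1 windows used
#'   for training; when the record provides more, an evenly spaced subset
#'   is taken (pure compute scaling — the mapping is stationary along the
#'   record).  `Inf` disables the cap.
#' @param seed integer RNG seed for initialization and batch shuffling.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(L = 150L, hidden = 30L, layers = 2L, epochs = 300L,
                         batch_size = 128L, learning_rate = 1e-3,
                         max_train_windows = 20000L, seed = 1L) {
  structure(list(L = as.integer(L), hidden = as.integer(hidden),
                 layers = as.integer(layers), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_train_windows = max_train_windows,
                 seed = as.integer(seed)),
            class = "synth_config")
}

standardize_fit <- function(v) {
  s <- stats::sd(v)
  list(center = mean(v), scale = if (is.finite(s) && s > 0) s else 1)
}

#' Train the patient-specific sliding-window LSTM VCG synthesizer
#'
#' Learns, for one record, the mapping from a length-`L` window of lead-I
#' samples to the synchronous Frank X, Y, Z samples.  Each window is an
#' independent training example (hidden state reset between windows); the
#' final hidden state of the top layer is linearly projected to the three
#' targets; mean squared error is minimized with Adam.  Inputs and
#' targets are standardized per record for conditioning; predictions are
#' returned in native units.
#'
#' @param record a preprocessed `multi_lead_record` with leads `i`, `vx`,
#'   `vy`, `vz`.
#' @param config a [synth_config()].
#' @return an object of class `vcg_synthesizer` with the layer weights,
#'   output projection, standardization constants, per-epoch loss history
#'   and the training config.
#' @export
train_synthesizer <- function(record, config = synth_config()) {
  x_raw <- get_lead(record, "i")
  Y_raw <- cbind(get_lead(record, "vx"), get_lead(record, "vy"),
                 get_lead(record, "vz"))
  if (length(x_raw) < 2L * config$L)
    stop("record too short: need at least ", 2L * config$L,
         " samples for window length ", config$L)

  xs <- standardize_fit(x_raw)
  ys <- apply(Y_raw, 2L, standardize_fit)
  x <- (x_raw - xs$center) / xs$scale
  Y <- sweep(sweep(Y_raw, 2L, vapply(ys, `[[`, 0, "center")), 2L,
             vapply(ys, `[[`, 0, "scale"), "/")

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  dims <- c(1L, rep(config$hidden, config$layers - 1L))
  params <- list(layers = lapply(seq_len(config$layers), function(l)
    init_lstm_layer(config$hidden, dims[l])),
    Wout = matrix(stats::rnorm(3L * config$hidden, 0,
                               1 / sqrt(config$hidden)), 3L, config$hidden),
    bout = rep(0, 3L))

  ends_all <- seq.int(config$L, length(x))
  if (length(ends_all) > config$max_train_windows) {
    ends_all <- ends_all[unique(round(seq(1L, length(ends_all),
                                          length.out = config$max_train_windows)))]
  }
  Yt <- Y[ends_all, , drop = FALSE]

  st <- adam_init(params)
  loss_hist <- numeric(config$epochs)
  nb <- max(1L, ceiling(length(ends_all) / config$batch_size))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(ends_all))
    ep_loss <- 0
    for (b in seq_len(nb)) {
      sel <- ord[seq.int((b - 1L) * config$batch_size + 1L,
                         min(b * config$batch_size, length(ends_all)))]
      gr <- cpp_lstm_loss_grad(params$layers, params$Wout, params$bout,
                               x, Yt[sel, , drop = FALSE], ends_all[sel],
                               config$L)
      ep_loss <- ep_loss + gr$loss * length(sel)
      upd <- adam_update(params,
                         list(layers = gr$layers, Wout = gr$Wout,
                              bout = gr$bout),
                         st, lr = config$learning_rate)
      params <- upd$params
      st <- upd$state
    }
    loss_hist[ep] <- ep_loss / length(ends_all)
  }

  structure(list(layers = params$layers, Wout = params$Wout,
                 bout = params$bout, L = config$L,
                 sampling_rate = record$sampling_rate,
                 x_center = xs$center, x_scale = xs$scale,
                 y_center = vapply(ys, `[[`, 0, "center"),
                 y_scale = vapply(ys, `[[`, 0, "scale"),
                 loss_history = loss_hist, config = config),
            class = "vcg_synthesizer")
}

#' Derive Frank XYZ leads from a lead-I sequence
#'
#' Applies a trained synthesizer to every stride-1 window of the input.
#' The output has `length(lead_i) - L + 1` samples per lead (one per
#' complete window) and lead names `vx_hat`, `vy_hat`, `vz_hat`.
#'
#' @param model a `vcg_synthesizer` or `mlp_synthesizer`.
#' @param lead_i numeric lead-I sequence (>= `L` samples).
#' @return a `multi_lead_record` with the three derived leads.
#' @export
derive_vcg <- function(model, lead_i) UseMethod("derive_vcg")

#' @export
derive_vcg.vcg_synthesizer <- function(model, lead_i) {
  if (length(lead_i) < model$L)
    stop("input shorter than the window length (", model$L, ")")
  x <- (lead_i - model$x_center) / model$x_scale
  ends <- seq.int(model$L, length(x))
  # chunked inference: keeps the per-step state matrices cache-resident,
  # which is several times faster than one huge batch
  chunk <- 1024L
  pred <- do.call(rbind, lapply(split(ends, ceiling(seq_along(ends) / chunk)),
                                function(e)
    cpp_lstm_forward(model$layers, model$Wout, model$bout, x, e, model$L)))
  pred <- sweep(sweep(pred, 2L, model$y_scale, "*"), 2L, model$y_center, "+")
  colnames(pred) <- c("vx_hat", "vy_hat", "vz_hat")
  multi_lead_record(pred, model$sampling_rate, "derived_vcg")
}

#' Train the feedforward baseline VCG synthesizer
#'
#' Same windowing, targets, loss and derive contract as
#' [train_synthesizer()], but the length-`L` window is flattened and fed
#' to a fully connected network (default 150-150-150-3, ReLU hidden
#' units, linear output).
#'
#' @param record a preprocessed `multi_lead_record` with leads `i`, `vx`,
#'   `vy`, `vz`.
#' @param config a [synth_config()]; `hidden` is the width of each of the
#'   two hidden layers (default here 150).
#' @return an object of class `mlp_synthesizer`.
#' @export
baseline_mlp_synthesizer <- function(record,
                                     config = synth_config(hidden = 150L)) {
  x_raw <- get_lead(record, "i")
  Y_raw <- cbind(get_lead(record, "vx"), get_lead(record, "vy"),
                 get_lead(record, "vz"))
  if (length(x_raw) < 2L * config$L)
    stop("record too short: need at least ", 2L * config$L,
         " samples for window length ", config$L)
  xs <- standardize_fit(x_raw)
  ys <- apply(Y_raw, 2L, standardize_fit)
  x <- (x_raw - xs$center) / xs$scale
  Y <- sweep(sweep(Y_raw, 2L, vapply(ys, `[[`, 0, "center")), 2L,
             vapply(ys, `[[`, 0, "scale"), "/")

  ends <- seq.int(config$L, length(x))
  if (length(ends) > config$max_train_windows)
    ends <- ends[unique(round(seq(1L, length(ends),
                                  length.out = config$max_train_windows)))]
  X <- window_matrix(x, ends, config$L)
  net <- dense_net_train(X, Y[ends, , drop = FALSE],
                         hidden = rep(config$hidden, 2L),
                         output = "identity", loss = "mse",
                         epochs = config$epochs,
                         batch_size = config$batch_size,
                         learning_rate = config$learning_rate,
                         seed = config$seed)
  structure(list(net = net, L = config$L,
                 sampling_rate = record$sampling_rate,
                 x_center = xs$center, x_scale = xs$scale,
                 y_center = vapply(ys, `[[`, 0, "center"),
                 y_scale = vapply(ys, `[[`, 0, "scale"),
                 loss_history = net$loss_history, config = config),
            class = "mlp_synthesizer")
}

#' @export
derive_vcg.mlp_synthesizer <- function(model, lead_i) {
  if (length(lead_i) < model$L)
    stop("input shorter than the window length (", model$L, ")")
  x <- (lead_i - model$x_center) / model$x_scale
  ends <- seq.int(model$L, length(x))
  pred <- dense_net_forward(model$net, window_matrix(x, ends, model$L))$output
  pred <- sweep(sweep(pred, 2L, model$y_scale, "*"), 2L, model$y_center, "+")
  colnames(pred) <- c("vx_hat", "vy_hat", "vz_hat")
  multi_lead_record(pred, model$sampling_rate, "derived_vcg_mlp")
}

# rows = windows, columns = lag L-1 .. 0 (oldest sample first)
window_matrix <- function(x, ends, L) {
  out <- matrix(0, length(ends), L)
  for (s in seq_len(L)) out[, s] <- x[ends - L + s]
  out
}

#' Root-mean-square error between measured and derived signals
#' @param v,v_hat equal-length numeric vectors.
#' @return non-negative scalar, in the signals' units.
#' @export
rmse <- function(v, v_hat) {
  if (length(v) != length(v_hat)) stop("length mismatch")
  if (length(v) < 1L) stop("need at least one sample")
  sqrt(mean((v - v_hat)^2))
}

#' Correlation coefficient between measured and derived signals
#'
#' The uncentered (cosine) form
#' `sum(v * v_hat) / sqrt(sum(v^2) * sum(v_hat^2))`: invariant to
#' positive rescaling of either argument but, deliberately, not to
#' constant shifts.
#'
#' @param v,v_hat equal-length numeric vectors, neither all-zero.
#' @return value in `[-1, 1]`; 1 iff `v_hat` is a positive multiple of `v`.
#' @export
cc <- function(v, v_hat) {
  if (length(v) != length(v_hat)) stop("length mismatch")
  n1 <- sqrt(sum(v^2)); n2 <- sqrt(sum(v_hat^2))
  if (n1 == 0 || n2 == 0) stop("cc undefined for an all-zero signal")
  max(-1, min(1, sum(v * v_hat) / (n1 * n2)))
}

#' Per-lead RMSE and CC between measured and derived Frank leads
#'
#' Signals are aligned at the end: the derived record is `L - 1` samples
#' shorter than the measured one, so the last `n_derived` samples of each
#' measured lead are compared.
#'
#' @param measured a record with leads `vx`, `vy`, `vz`.
#' @param derived a record with leads `vx_hat`, `vy_hat`, `vz_hat`.
#' @return data.frame with columns `lead`, `rmse`, `cc`.
#' @export
fidelity_report <- function(measured, derived) {
  nd <- n_samples(derived)
  nm <- n_samples(measured)
  if (nd > nm) stop("derived record longer than measured record")
  take <- (nm - nd + 1L):nm
  leads <- c("vx", "vy", "vz")
  data.frame(
    lead = paste0(leads, "_hat"),
    rmse = vapply(leads, function(l)
      rmse(get_lead(measured, l)[take],
           get_lead(derived, paste0(l, "_hat"))), numeric(1L)),
    cc = vapply(leads, function(l)
      cc(get_lead(measured, l)[take],
         get_lead(derived, paste0(l, "_hat"))), numeric(1L)),
    row.names = NULL)
}
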