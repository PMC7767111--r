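# Shared fixtures: everything is generated in code at test time.

# a clean (noise-free, wander-free, jitter-free) record: 60 bpm at 500 Hz
clean_record <- function(duration = 10, mean_rr = 1.0, seed = 42, ...) {
  generate_record(sim_config(duration, mean_rr = mean_rr, rr_jitter = 0,
                             noise_sd = 0, wander_amplitude = 0,
                             seed = seed, ...))
}

# random small LSTM layer parameters
rand_layer <- function(H, D, sd = 0.5) {
  mk <- function(r, co) matrix(stats::rnorm(r * co, 0, sd), r, co)
  list(Wf = mk(H, D), Wi = mk(H, D), Wc = mk(H, D), Wo = mk(H, D),
       Uf = mk(H, H), Ui = mk(H, H), Uc = mk(H, H), Uo = mk(H, H),
       bf = stats::rnorm(H, 0, sd), bi = stats::rnorm(H, 0, sd),
       bc = stats::rnorm(H, 0, sd), bo = stats::rnorm(H, 0, sd))
}

# independent scalar-loop oracle for a stack of LSTM layers + projection:
# composes exported lstm_step over the window, one window at a time
lstm_oracle_predict <- function(layers, Wout, bout, x, ends, L) {
  t(vapply(ends, function(e) {
    hs <- lapply(layers, function(l) rep(0, length(l$bf)))
    cs <- hs
    for (s in (e - L + 1L):e) {
      inp <- x[s]
      for (l in seq_along(layers)) {
        st <- lstm_step(layers[[l]], inp, hs[[l]], cs[[l]])
        hs[[l]] <- st$h; cs[[l]] <- st$c
        inp <- st$h
      }
    }
    as.numeric(Wout %*% hs[[length(layers)]] + bout)
  }, numeric(3L)))
}

# the known FIR mixing used in synthesis-recovery tests (3 x 30)
recovery_mixing <- function() {
  mix <- matrix(0, 3, 30)
  mix[1, 1] <- 0.8; mix[1, 6] <- -0.3
  mix[2, 1:21] <- 0.05
  mix[3, 11] <- 0.6; mix[3, 3] <- -0.4
  mix
}

extdata <- function(f) system.file("extdata", f, package = "vcgmi")
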