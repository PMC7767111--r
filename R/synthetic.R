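#' The 12 beat classes: 11 MI localizations plus healthy control
#'
#' Fixed label order used throughout the package (feature tables,
#' confusion matrices, classifier outputs).
#'
#' @return character vector of length 12.
#' @export
mi_classes <- function() {
  c("AMI", "ALMI", "ASMI", "ASLMI", "IMI", "ILMI",
    "IPMI", "IPLMI", "LMI", "PMI", "PLMI", "HC")
}

WAVE_NAMES <- c("P", "Q", "R", "S", "T")
AXIS_NAMES <- c("x", "y", "z")

#' Heartbeat morphology for the synthetic dipole model
#'
#' One cardiac cycle is modelled, per spatial axis, as a sum of five
#' Gaussian kernels (P, Q, R, S, T characteristic waves).  Amplitudes are
#' per axis; centers and widths are expressed as fractions of the RR
#' interval and may also differ per axis.
#'
#' @param amplitude 3 x 5 numeric matrix (rows x,y,z; columns P,Q,R,S,T),
#'   wave amplitudes in mV.
#' @param center 3 x 5 matrix (or length-5 vector recycled over axes) of
#'   wave centers, fractions of the RR interval, strictly increasing in
#'   (0, 1) along each row.
#' @param width 3 x 5 matrix (or length-5 vector) of Gaussian standard
#'   deviations, fractions of the RR interval, all > 0.
#' @return An object of class `beat_morphology`.
#' @export
beat_morphology <- function(amplitude, center, width) {
  to_mat <- function(v, what) {
    if (is.null(dim(v))) v <- matrix(v, nrow = 3L, ncol = 5L, byrow = TRUE)
    v <- as.matrix(v)
    if (!all(dim(v) == c(3L, 5L)))
      stop(what, " must be a 3 x 5 matrix (axes x,y,z by waves P,Q,R,S,T)")
    dimnames(v) <- list(AXIS_NAMES, WAVE_NAMES)
    v
  }
  amplitude <- to_mat(amplitude, "amplitude")
  center <- to_mat(center, "center")
  width <- to_mat(width, "width")
  if (any(width <= 0)) stop("wave widths must be > 0")
  if (any(center <= 0) || any(center >= 1))
    stop("wave centers must lie strictly inside (0, 1)")
  if (any(apply(center, 1L, function(r) any(diff(r) <= 0))))
    stop("wave centers must be strictly increasing (P < Q < R < S < T) on each axis")
  r_dominant <- any(vapply(1:3, function(a)
    amplitude[a, "R"] > max(abs(amplitude[a, setdiff(WAVE_NAMES, "R")])),
    logical(1L)))
  if (!r_dominant)
    stop("R amplitude must exceed all other wave amplitudes on at least one axis")
  structure(list(amplitude = amplitude, center = center, width = width),
            class = "beat_morphology")
}

#' Default healthy-control morphology
#'
#' Centers and widths are shared across axes so that every lead (a fixed
#' linear combination of the axes) peaks at the programmed R fiducial.
#'
#' @return a `beat_morphology`.
#' @export
default_morphology <- function() {
  amplitude <- rbind(
    x = c(P = 0.10, Q = -0.12, R = 1.20, S = -0.25, T = 0.35),
    y = c(P = 0.08, Q = -0.08, R = 0.90, S = -0.15, T = 0.25),
    z = c(P = 0.05, Q = -0.05, R = 0.60, S = -0.20, T = 0.20))
  beat_morphology(
    amplitude = amplitude,
    center = c(P = 0.18, Q = 0.28, R = 0.32, S = 0.36, T = 0.62),
    width  = c(P = 0.030, Q = 0.012, R = 0.015, S = 0.012, T = 0.060))
}

# Fixed per-class morphology offsets (mV), chosen so that each MI
# localization alters the axis its leads project onto: anterior/septal
# disease shows on the z axis, inferior on y, lateral on x, posterior as
# tall R / upright T on z.  Deterministic lookup so classifier tests are
# stable.
CLASS_PERTURBATIONS <- list(
  AMI   = list(c("z", "Q", -0.20), c("z", "T", -0.30)),
  ALMI  = list(c("z", "Q", -0.20), c("z", "T", -0.25), c("x", "T", -0.15)),
  ASMI  = list(c("z", "Q", -0.25), c("z", "R", -0.20), c("z", "T", -0.20)),
  ASLMI = list(c("z", "Q", -0.25), c("z", "T", -0.30), c("x", "Q", -0.10),
               c("x", "T", -0.15)),
  IMI   = list(c("y", "Q", -0.20), c("y", "T", -0.25)),
  ILMI  = list(c("y", "Q", -0.20), c("y", "T", -0.20), c("x", "T", -0.12)),
  IPMI  = list(c("y", "Q", -0.15), c("y", "T", -0.18), c("z", "R", 0.25)),
  IPLMI = list(c("y", "Q", -0.18), c("y", "T", -0.22), c("z", "R", 0.20),
               c("x", "T", -0.10)),
  LMI   = list(c("x", "Q", -0.18), c("x", "T", -0.22)),
  PMI   = list(c("z", "R", 0.30), c("z", "T", 0.15)),
  PLMI  = list(c("z", "R", 0.25), c("x", "Q", -0.12), c("x", "T", -0.15)),
  HC    = list())

#' Apply a deterministic class-conditional morphology perturbation
#'
#' Emulates the ECG signs of the eleven MI localization classes (deepened
#' Q waves, inverted or flattened T waves, tall posterior R waves) as
#' fixed amplitude offsets on class-specific axis subsets.  `"HC"` returns
#' the morphology unchanged.
#'
#' @param morphology a `beat_morphology`.
#' @param class_label one of [mi_classes()].
#' @return a perturbed `beat_morphology`.
#' @export
apply_class_perturbation <- function(morphology, class_label) {
  if (!inherits(morphology, "beat_morphology"))
    stop("morphology must be a beat_morphology")
  if (length(class_label) != 1L || !(class_label %in% mi_classes()))
    stop("unknown class label '", class_label, "'; expected one of: ",
         paste(mi_classes(), collapse = ", "))
  amp <- morphology$amplitude
  for (d in CLASS_PERTURBATIONS[[class_label]]) {
    amp[d[[1L]], d[[2L]]] <- amp[d[[1L]], d[[2L]]] + as.numeric(d[[3L]])
  }
  beat_morphology(amp, morphology$center, morphology$width)
}

#' Simulation configuration for the synthetic ECG generator
#'
#' @param duration record length in seconds (must be at least
#'   `3 * mean_rr`).
#' @param sampling_rate sampling rate in Hz (> 300).
#' @param mean_rr mean RR interval in seconds (default 0.8 s, the typical
#'   resting heartbeat length).
#' @param rr_jitter fractional uniform RR variability in `[0, 0.2]`;
#'   beat-to-beat RR is `mean_rr * (1 + rr_jitter * U[-1, 1])`.
#' @param lead_matrix 4 x 3 projection matrix (rows: lead I, Vx, Vy, Vz;
#'   columns: dipole axes x, y, z).  Default: lead I is the x axis
#'   rotated 15 degrees in the xy-plane; Frank rows are the identity.
#' @param noise_sd additive white-noise standard deviation in mV.
#' @param wander_amplitude baseline-wander amplitude in mV.
#' @param wander_freq baseline-wander frequency in Hz (respiratory band).
#' @param class_label beat class, one of [mi_classes()].
#' @param seed integer seed; the same config generates bit-identical
#'   records on every call.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration,
                       sampling_rate = 500,
                       mean_rr = 0.8,
                       rr_jitter = 0.05,
                       lead_matrix = default_lead_matrix(),
                       noise_sd = 0.02,
                       wander_amplitude = 0.1,
                       wander_freq = 0.3,
                       class_label = "HC",
                       seed = 1L) {
  if (sampling_rate <= 300) stop("sampling_rate must exceed 300 Hz")
  if (rr_jitter < 0 || rr_jitter > 0.2) stop("rr_jitter must lie in [0, 0.2]")
  lead_matrix <- as.matrix(lead_matrix)
  if (!all(dim(lead_matrix) == c(4L, 3L)))
    stop("lead_matrix must be 4 x 3 (leads I, Vx, Vy, Vz by axes x, y, z)")
  if (any(rowSums(abs(lead_matrix)) == 0))
    stop("every lead_matrix row must be non-zero")
  if (!(class_label %in% mi_classes()))
    stop("unknown class label '", class_label, "'")
  if (duration < 3 * mean_rr)
    stop("duration must cover at least 3 mean RR intervals (",
         3 * mean_rr, " s)")
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 mean_rr = mean_rr, rr_jitter = rr_jitter,
                 lead_matrix = lead_matrix, noise_sd = noise_sd,
                 wander_amplitude = wander_amplitude,
                 wander_freq = wander_freq, class_label = class_label,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default lead projection matrix
#'
#' Rows: lead I, Vx, Vy, Vz; columns: dipole axes x, y, z.  Lead I is the
#' x axis rotated 15 degrees towards y, so the single input lead carries
#' mixed-axis information; Frank rows are the identity.
#'
#' @return 4 x 3 numeric matrix.
#' @export
default_lead_matrix <- function() {
  th <- 15 * pi / 180
  m <- rbind(i = c(cos(th), sin(th), 0),
             vx = c(1, 0, 0),
             vy = c(0, 1, 0),
             vz = c(0, 0, 1))
  colnames(m) <- AXIS_NAMES
  m
}

#' Generate a seeded synthetic multi-lead ECG record
#'
#' All four leads (I, Vx, Vy, Vz) are projections of one 3-axis dipole
#' trajectory built from per-beat Gaussian P/Q/R/S/T kernels, plus
#' additive white noise and sinusoidal baseline wander.  Ground-truth
#' R-peak sample indices are returned alongside the signals.
#'
#' @param config a [sim_config()].
#' @param morphology a [beat_morphology()]; the config's `class_label`
#'   perturbation is applied on top via [apply_class_perturbation()].
#' @return A `multi_lead_record` (subclass `sim_record`) with leads
#'   `i`, `vx`, `vy`, `vz` and extra fields `r_peaks` (integer sample
#'   indices of the programmed R-wave centers), `dipole` (n x 3 matrix of
#'   the noiseless axis signals) and `morphology`.
#' @export
generate_record <- function(config, morphology = default_morphology()) {
  stopifnot(inherits(config, "sim_config"),
            inherits(morphology, "beat_morphology"))
  morphology <- apply_class_perturbation(morphology, config$class_label)
  fs <- config$sampling_rate
  n <- floor(config$duration * fs)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_beats <- ceiling(config$duration /
                       ((1 - config$rr_jitter) * config$mean_rr)) + 2L
  rr <- config$mean_rr * (1 + config$rr_jitter * runif(n_beats, -1, 1))
  bounds <- round(cumsum(c(0, rr)) * fs)  # beat k spans [bounds[k], bounds[k+1])

  phase <- numeric(n)
  beat_of <- findInterval(0:(n - 1L), bounds)  # 1-based beat index per sample
  for (k in seq_len(max(beat_of))) {
    sel <- beat_of == k
    nk <- bounds[k + 1L] - bounds[k]
    phase[sel] <- ((0:(n - 1L))[sel] - bounds[k]) / nk
  }

  dipole <- matrix(0, n, 3L, dimnames = list(NULL, AXIS_NAMES))
  for (a in 1:3) {
    for (w in 1:5) {
      dipole[, a] <- dipole[, a] + morphology$amplitude[a, w] *
        exp(-(phase - morphology$center[a, w])^2 /
              (2 * morphology$width[a, w]^2))
    }
  }

  signals <- dipole %*% t(config$lead_matrix)
  colnames(signals) <- rownames(config$lead_matrix)
  if (config$wander_amplitude > 0) {
    tt <- (0:(n - 1L)) / fs
    ph <- runif(4L, 0, 2 * pi)
    for (j in 1:4)
      signals[, j] <- signals[, j] + config$wander_amplitude *
        sin(2 * pi * config$wander_freq * tt + ph[j])
  }
  if (config$noise_sd > 0)
    signals <- signals + matrix(rnorm(length(signals), 0, config$noise_sd),
                                nrow = n)

  # programmed R fiducials: center of the R kernel in each complete beat
  k_full <- which(bounds[-1L] <= n)  # beats fully inside the record
  r_center <- mean(morphology$center[, "R"])
  r_peaks <- bounds[k_full] + round(r_center * diff(bounds)[k_full]) + 1L
  r_peaks <- r_peaks[r_peaks >= 1L & r_peaks <= n]

  rec <- multi_lead_record(signals, fs,
                           paste0("sim_", config$class_label, "_s", config$seed))
  rec$r_peaks <- as.integer(r_peaks)
  rec$dipole <- dipole
  rec$morphology <- morphology
  class(rec) <- c("sim_record", class(rec))
  rec
}

#' Replace Frank leads by known linear functionals of lead-I history
#'
#' Builds a record whose `vx`, `vy`, `vz` are exact causal FIR filters of
#' the record's lead I (`y_t^{(j)} = sum_s mixing[j, s] * x_{t-s+1}`).
#' Used to test that the window-based synthesizer can recover a known
#' ground-truth mapping.  The first `ncol(mixing) - 1` samples, where the
#' filter is not fully defined, are trimmed from all leads.
#'
#' @param record a `multi_lead_record` containing a lead named `"i"`.
#' @param mixing 3 x K numeric matrix of FIR coefficients (rows Vx, Vy,
#'   Vz; lag 0 in column 1).
#' @return a `multi_lead_record` with leads `i`, `vx`, `vy`, `vz`.
#' @export
linear_mixing_record <- function(record, mixing) {
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != 3L) stop("mixing must have 3 rows (vx, vy, vz)")
  x <- get_lead(record, "i")
  k <- ncol(mixing)
  if (length(x) <= k) stop("record shorter than the mixing filter")
  y <- vapply(1:3, function(j)
    as.numeric(stats::filter(x, mixing[j, ], method = "convolution",
                             sides = 1L)), numeric(length(x)))
  keep <- k:length(x)
  multi_lead_record(cbind(i = x[keep], vx = y[keep, 1L], vy = y[keep, 2L],
                          vz = y[keep, 3L]),
                    record$sampling_rate, paste0(record$record_id, "_mix"))
}
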