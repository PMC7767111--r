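#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic pipeline: 5-15 Hz band-pass, five-point derivative, squaring,
#' 150 ms moving-window integration, adaptive signal/noise thresholds
#' with a 200 ms refractory period and search-back at 1.66 times the
#' running RR average.  Detected fiducials are refined to the local
#' maximum of the input signal within +/- 75 ms.
#'
#' @param signal numeric vector (one lead).
#' @param fs sampling rate in Hz (>= 100).
#' @param params list of algorithm constants; see defaults in the source.
#' @return strictly increasing integer sample indices (possibly empty).
#' @export
detect_r_peaks <- function(signal, fs,
                           params = list(band = c(5, 15), band_order = 2L,
                                         mwi_ms = 150, refractory_ms = 200,
                                         search_ms = 75)) {
  if (fs < 100) stop("fs must be >= 100 Hz")
  n <- length(signal)
  if (n < 2 * fs) stop("signal must cover at least 2 s")
  if (all(signal == signal[1L])) return(integer(0))

  bp <- fft_filter(signal, fs, function(f)
    butter_zp_gain(f, params$band[1L], params$band[2L], params$band_order))
  # five-point derivative kernel (1/8)(2, 1, 0, -1, -2), centered
  der <- as.numeric(stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2L))
  der[is.na(der)] <- 0
  sq <- der^2
  mwi_n <- max(1L, round(params$mwi_ms / 1000 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / mwi_n, mwi_n), sides = 2L))
  integ[is.na(integ)] <- 0

  # candidate peaks: local maxima of the integrated signal
  d <- diff(integ)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(integer(0))

  refr <- round(params$refractory_ms / 1000 * fs)
  init <- integ[seq_len(min(n, 2L * round(fs)))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  qrs <- integer(0)
  rr_avg <- round(0.8 * fs)
  last <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    thr1 <- npki + 0.25 * (spki - npki)
    if (p - last >= refr && integ[p] > thr1) {
      qrs <- c(qrs, p)
      if (length(qrs) > 1L)
        rr_avg <- round(mean(diff(utils::tail(qrs, 8L))))
      spki <- 0.125 * integ[p] + 0.875 * spki
      last <- p
    } else if (p - last >= refr) {
      npki <- 0.125 * integ[p] + 0.875 * npki
      # search-back: no QRS for 1.66 RR -> accept best candidate above thr/2
      if (is.finite(last) && p - last > 1.66 * rr_avg) {
        back <- cand[cand > last + refr & cand <= p]
        if (length(back)) {
          bb <- back[which.max(integ[back])]
          if (integ[bb] > 0.5 * thr1) {
            qrs <- c(qrs, bb)
            spki <- 0.25 * integ[bb] + 0.75 * spki
            last <- bb
            qrs <- sort(qrs)
          }
        }
      }
    }
    i <- i + 1L
  }
  if (!length(qrs)) return(integer(0))

  # refine each fiducial to the local maximum of the raw signal
  w <- round(params$search_ms / 1000 * fs)
  peaks <- vapply(qrs, function(p) {
    lo <- max(1L, p - w); hi <- min(n, p + w)
    as.integer(lo + which.max(signal[lo:hi]) - 1L)
  }, integer(1L))
  peaks <- sort(unique(peaks))
  # enforce the refractory as minimum separation after refinement
  keep <- rep(TRUE, length(peaks))
  lastp <- peaks[1L]
  for (j in seq_along(peaks)[-1L]) {
    if (peaks[j] - lastp < refr) {
      keep[j] <- signal[peaks[j]] > signal[lastp]
      if (keep[j]) { keep[j - 1L] <- FALSE; lastp <- peaks[j] }
    } else lastp <- peaks[j]
  }
  as.integer(peaks[keep])
}

#' Segment a record into heartbeats between neighboring R peaks
#'
#' Beat `i` spans samples `[rpeaks[i], rpeaks[i+1])`; the same fiducials
#' are shared across all leads so per-beat features stay time-aligned.
#' Beats whose length falls outside the physiological RR bounds (0.2 s to
#' 3 s, i.e. 100-1500 samples at 500 Hz), or that overlap a filter edge
#' region, are dropped and counted.
#'
#' @param record a `multi_lead_record`.
#' @param rpeaks strictly increasing R-peak sample indices (>= 2).
#' @param min_rr,max_rr beat-length bounds in seconds.
#' @return a list of beats, each a list with `start`, `n` and `signals`
#'   (named list of per-lead sample vectors); the number of dropped beats
#'   is attached as attribute `"rejected"`.
#' @export
segment_beats <- function(record, rpeaks, min_rr = 0.2, max_rr = 3.0) {
  if (length(rpeaks) < 2L) stop("need at least 2 R peaks to segment beats")
  if (any(diff(rpeaks) <= 0)) stop("rpeaks must be strictly increasing")
  fs <- record$sampling_rate
  edge <- if (!is.null(record$edge_exclude)) record$edge_exclude else 0L
  n <- n_samples(record)
  lo <- round(min_rr * fs); hi <- round(max_rr * fs)
  beats <- list()
  rejected <- 0L
  for (k in seq_len(length(rpeaks) - 1L)) {
    a <- rpeaks[k]; b <- rpeaks[k + 1L]
    nk <- b - a
    if (nk < lo || nk > hi || a <= edge || b > n - edge + 1L) {
      rejected <- rejected + 1L
      next
    }
    sig <- lapply(seq_len(ncol(record$signals)), function(j)
      record$signals[a:(b - 1L), j])
    names(sig) <- colnames(record$signals)
    beats[[length(beats) + 1L]] <- list(start = a, n = nk, signals = sig)
  }
  attr(beats, "rejected") <- rejected
  beats
}

#' Period-normalize a beat to a fixed length
#'
#' Cubic-spline interpolation of the `N`-sample beat onto `target_len`
#' evenly spaced points over its support, with time scaling factor
#' `alpha = N / target_len`.
#'
#' @param samples numeric vector, the beat (>= 4 samples).
#' @param target_len output length (default 400, the nominal number of
#'   samples in a 0.8 s beat at 500 Hz).
#' @return list with `samples` (length `target_len`) and `alpha`.
#' @export
period_normalize <- function(samples, target_len = 400L) {
  n <- length(samples)
  if (n < 4L) stop("beat too short to interpolate (", n, " samples)")
  xout <- seq(0, n - 1L, length.out = target_len)
  list(samples = stats::spline(0:(n - 1L), samples, xout = xout,
                               method = "fmm")$y,
       alpha = n / target_len)
}

#' Min-max scale a sequence to [0, 1]
#'
#' Returns the scaled sequence and the amplitude scaling factor
#' `beta = max - min` (the offset `min` is discarded).
#'
#' @param samples numeric vector with `max > min`.
#' @return list with `samples` (in `[0, 1]`) and `beta`.
#' @export
minmax_scale <- function(samples) {
  lo <- min(samples); hi <- max(samples)
  if (!(hi > lo))
    stop("degenerate beat: constant sequence cannot be min-max scaled")
  list(samples = (samples - lo) / (hi - lo), beta = hi - lo)
}

#' Segment, period-normalize and scale all beats of a record
#'
#' Composition of [segment_beats()], [period_normalize()] and
#' [minmax_scale()] over the requested leads, sharing R fiducials across
#' leads.  Degenerate (constant) beats are rejected and counted.
#'
#' @param record a `multi_lead_record`.
#' @param rpeaks R-peak indices (e.g. from [detect_r_peaks()]).
#' @param leads leads to process (default: all).
#' @param target_len normalized beat length (default 400).
#' @return a list of normalized beats, each a list with `start`, `n`,
#'   `alpha` and `leads` (named list of `list(samples, beta)`); dropped
#'   beat count in attribute `"rejected"`.
#' @export
normalize_beats <- function(record, rpeaks, leads = lead_names(record),
                            target_len = 400L) {
  segs <- segment_beats(record, rpeaks)
  rejected <- attr(segs, "rejected")
  out <- list()
  for (beat in segs) {
    norm <- list(start = beat$start, n = beat$n,
                 alpha = beat$n / target_len, leads = list())
    ok <- TRUE
    for (l in leads) {
      pn <- period_normalize(beat$signals[[l]], target_len)
      sc <- tryCatch(minmax_scale(pn$samples), error = function(e) NULL)
      if (is.null(sc)) { ok <- FALSE; break }
      norm$leads[[l]] <- list(samples = sc$samples, beta = sc$beta)
    }
    if (ok) out[[length(out) + 1L]] <- norm else rejected <- rejected + 1L
  }
  attr(out, "rejected") <- rejected
  out
}
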