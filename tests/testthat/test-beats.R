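test_that("flat signal yields no R peaks", {
  expect_identical(detect_r_peaks(rep(0, 3000), 500), integer(0))
})

test_that("noiseless 60 bpm record: 10 peaks within 20 ms of ground truth", {
  rec <- clean_record(10, mean_rr = 1.0)
  p <- detect_r_peaks(get_lead(rec, "i"), 500)
  expect_length(p, 10L)
  err_ms <- vapply(rec$r_peaks, function(g) min(abs(p - g)) / 500 * 1000,
                   numeric(1L))
  expect_true(all(err_ms <= 20))
})

test_that("noisy record: >= 95% of ground-truth peaks matched within 30 ms", {
  cfg <- sim_config(30, mean_rr = 0.8, rr_jitter = 0.05, noise_sd = 0.05,
                    wander_amplitude = 0.1, seed = 3)
  rec <- generate_record(cfg)
  pp <- preprocess_record(rec)
  p <- detect_r_peaks(get_lead(pp, "i"), 500)
  hit <- vapply(rec$r_peaks, function(g) any(abs(p - g) <= 15), logical(1L))
  expect_gte(mean(hit), 0.95)
  expect_true(all(diff(p) >= 100))  # 200 ms refractory at 500 Hz
})

test_that("segmentation counts beats and applies RR bounds", {
  rec <- clean_record(10, mean_rr = 1.0)
  peaks5 <- rec$r_peaks[1:5]
  expect_length(segment_beats(rec, peaks5), 4L)

  segs <- segment_beats(rec, c(1L, 401L, 801L))
  expect_length(segs, 2L)
  expect_true(all(vapply(segs, `[[`, 0L, "n") == 400L))

  # 190-sample RR (0.38 s) kept; 80-sample RR dropped
  segs2 <- segment_beats(rec, c(1001L, 1191L, 1271L))
  expect_length(segs2, 1L)
  expect_identical(segs2[[1L]]$n, 190L)
  expect_identical(attr(segs2, "rejected"), 1L)
  expect_error(segment_beats(rec, 42L), "at least 2")
})

test_that("period normalization: identity length, alpha, sine oracle", {
  rec <- clean_record(10, mean_rr = 0.8, seed = 6)
  beat <- get_lead(rec, "vx")[1:400]
  pn <- period_normalize(beat)
  expect_identical(pn$alpha, 1.0)
  expect_lt(max(abs(pn$samples - beat)), 1e-9)

  expect_identical(period_normalize(beat[1:360])$alpha, 0.9)

  u <- (0:49) / 49
  pn2 <- period_normalize(sin(2 * pi * u), target_len = 400L)
  u_new <- seq(0, 1, length.out = 400L)
  expect_lt(max(abs(pn2$samples - sin(2 * pi * u_new))), 1e-4)
  expect_error(period_normalize(c(1, 2, 3)), "too short")
})

test_that("alpha recovery: normalizing then resampling back is near-identity", {
  rec <- clean_record(10, mean_rr = 0.8, seed = 6)
  beat <- get_lead(rec, "vx")[30:420]  # N = 391
  pn <- period_normalize(beat)
  back <- stats::spline(seq(0, 390, length.out = 400L), pn$samples,
                        xout = 0:390, method = "fmm")$y
  expect_lt(max(abs(back - beat)), 1e-3)
})

test_that("min-max scaling and its degenerate case", {
  sc <- minmax_scale(c(2, 4, 6))
  expect_equal(sc$samples, c(0, 0.5, 1))
  expect_identical(sc$beta, 4)
  v <- c(0, 0.25, 1, 0.5)
  sc2 <- minmax_scale(v)
  expect_identical(sc2$samples, v)
  expect_identical(sc2$beta, 1)
  expect_error(minmax_scale(rep(2, 10)), "degenerate")
})

test_that("normalize_beats: counts preserved, fiducials shared, range [0,1]", {
  cfg <- sim_config(30, mean_rr = 0.8, rr_jitter = 0.05, noise_sd = 0.02,
                    wander_amplitude = 0.1, seed = 8)
  rec <- generate_record(cfg)
  pp <- preprocess_record(rec)
  p <- detect_r_peaks(get_lead(pp, "i"), 500)
  segs <- segment_beats(pp, p)
  beats <- normalize_beats(pp, p, leads = c("vx", "vy", "vz"))
  expect_identical(length(segs) + attr(segs, "rejected"),
                   length(beats) + attr(beats, "rejected"))
  for (b in beats[1:3]) {
    expect_identical(b$alpha, b$n / 400)
    for (l in names(b$leads)) {
      expect_length(b$leads[[l]]$samples, 400L)
      expect_equal(range(b$leads[[l]]$samples), c(0, 1), tolerance = 1e-9)
    }
  }
  # fiducial sharing: every beat spans identical [start, start + n) per lead
  expect_true(all(vapply(beats, function(b)
    length(unique(vapply(b$leads, function(l) length(l$samples), 0L))) == 1L,
    logical(1L))))
})
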