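make_raw <- function(values, rate = 10) pupil_trace(values, rate_hz = rate)

test_that("preprocessing produces the documented grid and state", {
  withr::with_seed(1, {
    x <- cumsum(rnorm(6000)) / 50 + 5
  })
  tr <- preprocess_pupil(make_raw(x))
  expect_equal(length(tr$values), 60000L)
  expect_equal(tr$rate_hz, 100)
  expect_true(all(c("zscored", "upsampled", "highpassed") %in% tr$state))
  expect_true(all(is.finite(tr$values)))
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(preprocess_pupil(make_raw(rep(3, 500))), "degenerate variance")
  expect_error(preprocess_pupil(make_raw(rnorm(100))), "shorter than 20 s")
  x <- rnorm(600)
  expect_error(preprocess_pupil(make_raw(x), blink_intervals =
                                  cbind(2, 45)), "half the trace")
})

test_that("blink gaps are bridged linearly between the flanking samples", {
  x <- sin(2 * pi * 0.05 * (0:599) / 10)
  x[101:120] <- 50 # corrupted segment: samples at 10.0 .. 11.9 s
  tr <- make_raw(x)
  out <- preprocess_pupil(tr, blink_intervals = cbind(9.95, 11.95))
  # compare against preprocessing of the hand-interpolated trace
  xi <- x
  anchor_pre <- x[100]
  anchor_post <- x[121]
  xi[101:120] <- anchor_pre + (anchor_post - anchor_pre) * (1:20) / 21
  ref <- preprocess_pupil(make_raw(xi))
  expect_equal(out$values, ref$values, tolerance = 1e-6)
})

test_that("slow drift is attenuated at least as much as the analytic filter", {
  # 0.05 Hz sinusoid vs 4th-order high-pass at 0.1 Hz, applied zero-phase:
  # |H|^2 with |H| = u^4/sqrt(1+u^8), u = f/fc
  t <- (0:5999) / 10
  x <- sin(2 * pi * 0.05 * t)
  tr <- preprocess_pupil(make_raw(x))
  u <- 0.05 / 0.1
  h2 <- (u^4 / sqrt(1 + u^8))^2
  mid <- 10000:50000
  # after z-scoring the sinusoid has unit RMS, so the interior output RMS is
  # directly comparable to the squared one-pass magnitude (factor 2 covers
  # spline and edge residue)
  expect_lt(sqrt(mean(tr$values[mid]^2)), 2 * h2)
})

test_that("preprocessing is zero-phase: time reversal commutes", {
  withr::with_seed(2, x <- cumsum(rnorm(6000)) / 30)
  fwd <- preprocess_pupil(make_raw(x))$values
  bwd <- preprocess_pupil(make_raw(rev(x)))$values
  # the upsampled grid runs [0, N/10) so the reversed run samples times
  # shifted by 9 output samples; compare at matched absolute times and
  # exclude the filter settling spans at both ends
  keep <- 16000:44000
  expect_lt(max(abs(rev(bwd)[keep + 9L] - fwd[keep])), 1e-8)
})

test_that("detector finds nothing on flat traces and single bumps exactly once", {
  expect_equal(nrow(detect_spontaneous_dilations(
    as_preprocessed_trace(numeric(30000)))), 0L)

  t <- (0:59999) / 100
  bump <- 2 * exp(-(t - 50)^2 / (2 * 0.5^2))
  ev <- detect_spontaneous_dilations(as_preprocessed_trace(bump))
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$peak_time_s - 50), 0.01)
  bf <- brute_force_detect(bump)
  expect_identical(ev$peak_index, bf$peak_index)
})

test_that("dilations that fail the 6 s return rule are rejected", {
  t <- (0:59999) / 100
  # rises fast, stays above 0.5 z for ~9.2 s after the peak
  slow <- ifelse(t < 50, 2 * exp(-(t - 50)^2 / (2 * 0.5^2)),
                 2 * exp(-(t - 50) / 6.7))
  expect_gt(min(slow[t > 50 & t < 58]), 0.5)
  ev <- detect_spontaneous_dilations(as_preprocessed_trace(slow))
  expect_equal(nrow(ev), 0L)
})

test_that("detection contract errors fire on wrong state or rate", {
  tr <- pupil_trace(numeric(30000), rate_hz = 100, state = "raw")
  expect_error(detect_spontaneous_dilations(tr), "contract error")
  tr2 <- as_preprocessed_trace(numeric(3000), rate_hz = 10)
  expect_error(detect_spontaneous_dilations(tr2), "contract error")
})

test_that("every returned event re-satisfies the three printed criteria", {
  for (s in c(31, 32)) {
    tr <- random_detector_trace(s, duration_s = 300)
    x <- tr$values
    ev <- detect_spontaneous_dilations(tr)
    for (r in seq_len(nrow(ev))) {
      pk <- ev$peak_index[r]
      i0 <- round(ev$onset_start_s[r] * 100) + 1L
      expect_true(all(x[i0:(i0 + 199)] < 0.5))       # quiet pre-window
      expect_gt(x[pk], 0.5)                          # supra-threshold peak
      expect_true(any(x[(pk + 1):(pk + 600)] < 0.5)) # returns within 6 s
    }
  }
})

test_that("event sets nest across detection thresholds", {
  ses <- simulate_session(sim_config(duration_s = 600, stim_interval_s = Inf,
                                     seed = 21))
  tr <- preprocess_pupil(ses$pupil)
  evs <- lapply(c(0.5, 0.65, 1.0), function(th) {
    detect_spontaneous_dilations(tr, detection_config(threshold_sd = th))
  })
  nested <- function(small, big) {
    all(vapply(small$peak_time_s, function(t) {
      any(abs(big$peak_time_s - t) <= 0.2)
    }, logical(1)))
  }
  expect_true(nested(evs[[3]], evs[[2]]))
  expect_true(nested(evs[[2]], evs[[1]]))
})

test_that("sliding detector matches the brute-force oracle on random traces", {
  for (s in 41:45) {
    tr <- random_detector_trace(s, duration_s = 300)
    ev <- detect_spontaneous_dilations(tr)
    bf <- brute_force_detect(tr$values)
    expect_identical(ev$peak_index, bf$peak_index)
    expect_identical(attr(ev, "dropped"), bf$dropped)
  }
})

test_that("event metrics match direct window averaging", {
  # constant trace: baseline = c, amplitude = 0
  tr <- as_preprocessed_trace(rep(0.37, 3000))
  m <- compute_event_metrics(tr, 15)
  expect_equal(unname(m["baseline_z"]), 0.37)
  expect_equal(unname(m["amplitude_z"]), 0)

  # piecewise construction: baseline 0.1, amplitude window mean 1.2
  t <- (0:2999) / 100
  x <- numeric(3000)
  x[t >= 9 & t < 11] <- 0.1       # [-6, -4) relative to peak at 15 s
  x[t >= 12.5 & t < 17.5] <- 1.2  # [-2.5, 2.5)
  m <- compute_event_metrics(as_preprocessed_trace(x), 15)
  expect_equal(unname(m["baseline_z"]), 0.1)
  expect_equal(unname(m["amplitude_z"]), 1.1)

  # random trace: equal to the independent windowed-mean loop
  withr::with_seed(6, x <- rnorm(3000))
  tr <- as_preprocessed_trace(x)
  m <- compute_event_metrics(tr, 15)
  b_ref <- brute_force_metrics(x, 100, 0, 15, c(-6, -4))
  a_ref <- brute_force_metrics(x, 100, 0, 15, c(-2.5, 2.5)) - b_ref
  expect_equal(unname(m["baseline_z"]), b_ref)
  expect_equal(unname(m["amplitude_z"]), a_ref)

  expect_error(compute_event_metrics(tr, 2), "boundary error")
})

test_that("evoked peaks are located at the planted maxima", {
  cfg <- sim_config(duration_s = 600, slow_noise_sd = 0, seed = 8)
  ses <- simulate_session(cfg)
  tr <- preprocess_pupil(ses$pupil)
  ev <- locate_evoked_peaks(tr, ses$stim_onsets)
  expect_equal(nrow(ev) + attr(ev, "dropped"), length(ses$stim_onsets))
  # evoked latency 2.5 s; the high-pass shifts the transient peak slightly
  lat <- ev$peak_time_s - ses$stim_onsets[
    vapply(ev$peak_time_s, function(t) which.min(abs(ses$stim_onsets - t)),
           integer(1))]
  expect_true(all(abs(lat - 2.5) < 0.5))
  expect_true(all(ev$label == "evoked"))
})

test_that("evoked location on a flat trace ties to the first sample", {
  tr <- as_preprocessed_trace(numeric(20000)) # 200 s
  ev <- locate_evoked_peaks(tr, c(50, 100))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$amplitude_z, c(0, 0))
  # tie-break: first sample strictly after the onset
  expect_equal(ev$peak_time_s, c(50.01, 100.01))
  expect_warning(locate_evoked_peaks(tr, c(50, 53)), "overlapping")
})

test_that("peak alignment extracts exact half-open windows", {
  ramp <- list(values = (0:59999) / 100, rate_hz = 100, t0_s = 0)
  ev <- dilation_events(peak_time_s = 50, peak_index = 5001L,
                        label = "spontaneous", baseline_z = 0,
                        amplitude_z = 0, onset_start_s = 0, onset_end_s = 0)
  al <- align_to_peaks(ramp, ev, halfspan_s = 6)
  expect_equal(ncol(al$matrix), 1200L)
  expect_equal(al$matrix[1, ], seq(44, 55.99, by = 0.01))
  expect_equal(al$times_rel_s[1], -6)

  # boundary violation is dropped and counted
  ev2 <- dilation_events(peak_time_s = c(3, 50), peak_index = c(301L, 5001L),
                         label = c("spontaneous", "spontaneous"),
                         baseline_z = c(0, 0), amplitude_z = c(0, 0),
                         onset_start_s = c(0, 0), onset_end_s = c(0, 0))
  al2 <- align_to_peaks(ramp, ev2, halfspan_s = 6)
  expect_equal(nrow(al2$matrix), 1L)
  expect_equal(al2$dropped, 1L)

  # empty event list: zero-row matrix
  al3 <- align_to_peaks(ramp, dilation_events(), halfspan_s = 6)
  expect_equal(nrow(al3$matrix), 0L)
})
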