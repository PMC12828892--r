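test_that("window periodogram is Parseval-consistent and localizes sinusoids", {
  expect_error(window_psd(numeric(999)), "contract error")
  expect_true(all(window_psd(numeric(1000))$psd == 0))

  # unit 10 Hz sine: dominant bin at 10 Hz, integral = mean square = 0.5
  s <- window_psd(sin(2 * pi * 10 * (0:999) / 1000))
  expect_equal(sum(s$psd) * 1, 0.5, tolerance = 1e-12)
  expect_gte(s$psd[s$freqs == 10] / sum(s$psd), 0.99)

  # random windows: sum(psd)*df equals the mean squared signal exactly
  withr::with_seed(3, {
    for (r in 1:20) {
      x <- rnorm(1000, sd = runif(1, 0.5, 3))
      s <- window_psd(x)
      expect_lt(abs(sum(s$psd) - mean(x^2)) / mean(x^2), 1e-6)
    }
  })
})

test_that("band AUC integrates the right bins and is additive", {
  zero <- window_psd(numeric(1000))
  bands <- canonical_bands()
  for (i in seq_len(nrow(bands))) {
    expect_equal(band_auc(zero, bands[i, ]), 0)
  }
  s <- window_psd(sin(2 * pi * 10 * (0:999) / 1000))
  tot <- band_auc(s, list(f_lo = 1, f_hi = 100))
  expect_gte(band_auc(s, bands[bands$name == "alpha", ]) / tot, 0.95)
  # canonical edges route sinusoids into their bands
  s2 <- window_psd(sin(2 * pi * 2 * (0:999) / 1000))
  fr2 <- vapply(seq_len(nrow(bands)), function(i) band_auc(s2, bands[i, ]),
                numeric(1))
  expect_equal(bands$name[which.max(fr2)], "delta")
  s70 <- window_psd(sin(2 * pi * 70 * (0:999) / 1000))
  fr70 <- vapply(seq_len(nrow(bands)), function(i) band_auc(s70, bands[i, ]),
                 numeric(1))
  expect_equal(bands$name[which.max(fr70)], "high_gamma")

  # additivity when the split point is a grid point
  withr::with_seed(4, s3 <- window_psd(rnorm(1000)))
  expect_equal(band_auc(s3, list(f_lo = 5, f_hi = 40)),
               band_auc(s3, list(f_lo = 5, f_hi = 20)) +
                 band_auc(s3, list(f_lo = 20, f_hi = 40)),
               tolerance = 1e-12)
})

test_that("EEG filtering attenuates per the analytic responses", {
  t <- (0:19999) / 1000
  # 150 Hz: one-pass 6th-order magnitude at u = 1.5 is 1/sqrt(1+1.5^12);
  # zero-phase application squares it
  x150 <- eeg_trace(sin(2 * pi * 150 * t))
  out <- preprocess_eeg(x150, notch_hz = NA)
  h2 <- 1 / (1 + 1.5^12)
  mid <- 3000:17000
  expect_lt(sqrt(mean(out$values[mid]^2)) / sqrt(0.5), 1.5 * h2)
  expect_equal(out$state, "filtered")

  # 60 Hz mains: notch leaves < 5% of the input RMS
  x60 <- eeg_trace(sin(2 * pi * 60 * t))
  out60 <- preprocess_eeg(x60)
  expect_lt(sqrt(mean(out60$values[mid]^2)) / sqrt(0.5), 0.05)

  # white noise: mean preserved near zero, low band minimally shaped
  withr::with_seed(5, xw <- eeg_trace(rnorm(20000)))
  outw <- preprocess_eeg(xw)
  expect_lt(abs(mean(outw$values)), 0.05)

  expect_error(preprocess_eeg(eeg_trace(rnorm(2000))), "shorter than 5 s")
})

test_that("sliding band power has the documented length, grid and values", {
  withr::with_seed(6, eeg <- eeg_trace(rnorm(61000)))
  eeg$state <- "filtered"
  bp <- sliding_band_power(eeg)
  expect_equal(length(bp$delta$values), 6001L)
  expect_equal(bp$delta$rate_hz, 100)
  expect_equal(bp$delta$t0_s, 0.5) # centre of the first 1 s window

  # dual-route check: series values equal window_psd + band_auc directly
  bands <- canonical_bands()
  for (w in c(1L, 57L, 4201L)) {
    i0 <- (w - 1L) * 10L + 1L
    spec <- window_psd(eeg$values[i0:(i0 + 999L)])
    for (b in seq_len(nrow(bands))) {
      expect_equal(bp[[bands$name[b]]]$values[w], band_auc(spec, bands[b, ]),
                   tolerance = 1e-10)
    }
  }

  # zero signal: all-zero series
  z <- eeg_trace(numeric(5000)); z$state <- "filtered"
  bpz <- sliding_band_power(z)
  expect_true(all(vapply(bpz, function(s) all(s$values == 0), logical(1))))
})

test_that("band power tracks the squared amplitude of an oscillation", {
  t <- (0:59999) / 1000
  amp <- ifelse(t < 30, 1, 2)
  eeg <- eeg_trace(amp * sin(2 * pi * 10 * t)) # amplitude doubles at 30 s
  eeg$state <- "filtered"
  alpha <- sliding_band_power(eeg)$alpha$values
  early <- mean(alpha[500:2000])
  late <- mean(alpha[4000:5500])
  expect_equal(late / early, 4, tolerance = 0.05)
})

test_that("band-power series share the pupil timebase", {
  ses <- simulate_session(sim_config(duration_s = 60, stim_interval_s = Inf,
                                     seed = 10))
  pupil <- preprocess_pupil(ses$pupil)
  eeg <- preprocess_eeg(ses$eeg)
  bp <- sliding_band_power(eeg)
  t_b <- bp$delta$t0_s + (seq_along(bp$delta$values) - 1) / bp$delta$rate_hz
  t_p <- pupil$t0_s + (seq_along(pupil$values) - 1) / pupil$rate_hz
  # 100 Hz grids; the band series starts half a window in
  expect_equal(bp$delta$rate_hz, pupil$rate_hz)
  common <- intersect(round(t_b * 100), round(t_p * 100))
  expect_equal(length(common), length(t_b))
})

test_that("session-level normalized PSD behaves as a distribution", {
  ses <- simulate_session(sim_config(duration_s = 300, stim_interval_s = Inf,
                                     seed = 12))
  eeg <- preprocess_eeg(ses$eeg)
  np <- session_normalized_psd(eeg, n_segments = 50, seed = 2)
  # six band fractions can at most tile [1, 100] minus the gaps
  expect_lte(sum(np$band_fractions), 1)
  expect_true(all(np$band_fractions > 0))
  # normalized spectrum integrates to 1 over 1-100 Hz
  expect_equal(band_auc(np$spectrum, list(f_lo = 1, f_hi = 100)), 1,
               tolerance = 1e-9)

  # scale invariance
  eeg2 <- eeg_trace(eeg$values * 7.3, state = "filtered")
  np2 <- session_normalized_psd(eeg2, n_segments = 50, seed = 2)
  expect_equal(np2$spectrum$psd, np$spectrum$psd, tolerance = 1e-12)
  expect_equal(np2$band_fractions, np$band_fractions, tolerance = 1e-12)

  expect_error(session_normalized_psd(eeg, n_segments = 1000),
               "insufficient data")
})

test_that("stronger gamma drive raises the high-gamma fraction", {
  mk <- function(gain, seed) {
    bc <- default_band_coupling()
    bc$osc_sd_uv[bc$band == "high_gamma"] <-
      bc$osc_sd_uv[bc$band == "high_gamma"] * gain
    cfg <- sim_config(duration_s = 200, stim_interval_s = Inf,
                      band_coupling = bc, seed = seed)
    eeg <- preprocess_eeg(simulate_eeg(cfg, numeric(0), character(0)))
    session_normalized_psd(eeg, n_segments = 50, seed = 3)$band_fractions
  }
  expect_gt(mk(2, 14)[["high_gamma"]], mk(1, 14)[["high_gamma"]])
})

test_that("aperiodic parameterization recovers knee spectra and peaks", {
  f <- 1:100
  for (chi in c(0.5, 1, 1.5, 2)) {
    for (k in c(0, 10)) {
      s <- spectrum_estimate(f, 10^1.2 / (k + f^chi), 1)
      fit <- fit_aperiodic(s)
      expect_lt(abs(fit$exponent - chi), 0.05)
      expect_lt(abs(fit$offset - 1.2), 0.05)
      expect_equal(nrow(fit$peaks), 0L)
    }
  }

  # flat spectrum: exponent ~ 0, offset ~ log10(level)
  sflat <- spectrum_estimate(f, rep(0.5, 100), 1)
  fit <- fit_aperiodic(sflat)
  expect_lt(abs(fit$exponent), 1e-3)
  expect_lt(abs(fit$offset - log10(0.5)), 0.05)

  # one Gaussian peak: exactly one reported, centre within 0.5 Hz
  L <- 1 - log10(10 + f^2) + 0.5 * exp(-(f - 10)^2 / (2 * 1.5^2))
  fit <- fit_aperiodic(spectrum_estimate(f, 10^L, 1))
  expect_equal(nrow(fit$peaks), 1L)
  expect_lt(abs(fit$peaks$center_hz - 10), 0.5)
  expect_lt(abs(fit$peaks$height - 0.5), 0.1)
  expect_gt(fit$r_squared, 0.999)

  expect_error(fit_aperiodic(spectrum_estimate(1:3, c(1, 1, 1), 1)),
               "fit range")
})
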