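test_that("pupil simulation honours the null case and kernel geometry", {
  cfg <- sim_config(duration_s = 100, stim_interval_s = Inf,
                    event_amp_z = 0, slow_noise_sd = 0, seed = 1)
  expect_true(all(simulate_pupil(cfg, c(30, 60))$values == 0))

  # single noiseless event: trace max at the event time with peak = amplitude
  cfg <- sim_config(duration_s = 100, stim_interval_s = Inf,
                    event_amp_z = 1.7, slow_noise_sd = 0,
                    kernel_rise_s = 0.5, kernel_decay_s = 2, seed = 1)
  tr <- simulate_pupil(cfg, 50)
  i_max <- which.max(tr$values)
  expect_lte(abs((i_max - 1) / tr$rate_hz - 50), 1 / tr$rate_hz)
  expect_equal(max(tr$values), 1.7, tolerance = 1e-8)

  expect_error(simulate_pupil(cfg, 50, amps = -1), "negative")
  expect_error(simulate_pupil(cfg, 150), "inside")
})

test_that("planted event counts fall in the central 99% Poisson interval", {
  # lambda = duration * rate = 60; qpois(c(0.005, 0.995), 60) = [41, 81]
  cfg <- sim_config(duration_s = 1800, stim_interval_s = Inf, seed = 11)
  n_ev <- nrow(simulate_session(cfg)$truth_events)
  expect_gte(n_ev, 41)
  expect_lte(n_ev, 81)
})

test_that("sessions are bit-for-bit reproducible from the seed", {
  cfg <- sim_config(duration_s = 120, seed = 5)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$pupil$values, b$pupil$values)
  expect_identical(a$eeg$values, b$eeg$values)
  expect_identical(a$truth_events, b$truth_events)
  expect_identical(a$stim_onsets, b$stim_onsets)
})

test_that("stimulation layout and event-placement invariants hold", {
  cfg <- sim_config(duration_s = 600, seed = 2)
  ses <- simulate_session(cfg)
  n_stim <- length(ses$stim_onsets)
  expect_true(n_stim %in% c(19L, 20L))
  ev <- ses$truth_events
  expect_true(all(ev$peak_time_s >= 0 & ev$peak_time_s <= 600))
  # every evoked event follows a stimulation onset at the configured latency
  evo <- ev$peak_time_s[ev$label == "evoked"]
  expect_equal(length(evo), n_stim)
  expect_true(all(vapply(evo, function(t) {
    any(abs(t - ses$stim_onsets - cfg$evoked_latency_s) < 1e-9)
  }, logical(1))))
  # spontaneous events were thinned away from the stimulation onsets
  sp <- ev$peak_time_s[ev$label == "spontaneous"]
  expect_true(all(vapply(sp, function(t) {
    all(abs(t - ses$stim_onsets) >= 10)
  }, logical(1))))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(duration_s = 10), "kernel spans")
  expect_error(sim_config(duration_s = 600, event_rate_per_s = 1 / 1000),
               "at least 1")
  expect_error(sim_config(aperiodic_exponent = -1), "exponent")
  expect_error(sim_config(event_amp_z = -0.5), "negative")
  bc <- default_band_coupling()
  bc$gain_evoked[1] <- -1.5
  expect_error(sim_config(band_coupling = bc), "below -1")
})

test_that("aperiodic generator/fit round-trip recovers the exponent", {
  # single-case check at the documented condition (300 s, chi = 1.5, k = 0)
  cfg <- sim_config(duration_s = 300, stim_interval_s = Inf,
                    band_coupling = NULL, aperiodic_offset = 1.5,
                    aperiodic_knee = 0, aperiodic_exponent = 1.5, seed = 3)
  eeg <- simulate_eeg(cfg, numeric(0), character(0))
  acc <- 0
  for (w in seq_len(300)) {
    acc <- acc + window_psd(eeg$values[((w - 1) * 1000 + 1):(w * 1000)])$psd
  }
  spec <- spectrum_estimate(0:500, acc / 300, 1)
  fit <- fit_aperiodic(spec)
  expect_lt(abs(fit$exponent - 1.5), 0.1)
})

test_that("offset and exponent recover across seeds (noise-only EEG)", {
  # renewal of the round-trip over many seeds, 120 s each
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(duration_s = 120, stim_interval_s = Inf,
                      band_coupling = NULL, aperiodic_offset = 1.2,
                      aperiodic_knee = 10, aperiodic_exponent = 1.8,
                      seed = 1000 + s)
    eeg <- simulate_eeg(cfg, numeric(0), character(0))
    acc <- 0
    for (w in seq_len(120)) {
      acc <- acc + window_psd(eeg$values[((w - 1) * 1000 + 1):(w * 1000)])$psd
    }
    fit <- fit_aperiodic(spectrum_estimate(0:500, acc / 120, 1))
    if (abs(fit$exponent - 1.8) <= 0.1 && abs(fit$offset - 1.2) <= 0.1) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95L)
})

test_that("stronger evoked high-gamma coupling raises peri-peak gamma power", {
  bc <- default_band_coupling(
    gain_spontaneous = c(high_gamma = 1.0),
    gain_evoked = c(high_gamma = 2.0))
  cfg <- sim_config(duration_s = 400, stim_interval_s = Inf,
                    band_coupling = bc, seed = 9)
  peaks <- seq(20, 380, by = 18)
  labels <- rep(c("spontaneous", "evoked"), length.out = length(peaks))
  eeg <- preprocess_eeg(simulate_eeg(cfg, peaks, labels))
  hg <- sliding_band_power(eeg)$high_gamma
  ev <- dilation_events(peak_time_s = peaks,
                        peak_index = round(peaks * 100) + 1L,
                        label = labels,
                        baseline_z = NA_real_, amplitude_z = NA_real_,
                        onset_start_s = NA_real_, onset_end_s = NA_real_)
  al <- align_to_peaks(hg, ev, halfspan_s = 2.5)
  in_win <- rowMeans(al$matrix)
  expect_gt(mean(in_win[al$events$label == "evoked"]),
            mean(in_win[al$events$label == "spontaneous"]))
})

test_that("uncoupled bands show no correlation with the event kernel", {
  bc <- default_band_coupling()
  bc$gain_spontaneous[] <- 0
  bc$gain_evoked[] <- 0
  cfg <- sim_config(duration_s = 300, band_coupling = bc,
                    stim_interval_s = Inf, seed = 13)
  peaks <- seq(20, 280, by = 15)
  eeg <- preprocess_eeg(simulate_eeg(cfg, peaks, rep("spontaneous",
                                                     length(peaks))))
  bp <- sliding_band_power(eeg)
  t_bp <- bp$high_gamma$t0_s + (seq_along(bp$high_gamma$values) - 1) / 100
  kern <- pupilstate:::kernel_train(t_bp, peaks, rep(1, length(peaks)),
                                    0.5, 2)
  # 95% null bound for a correlation at this many effective samples: the
  # band-power series decorrelates within ~1 s, so use a conservative bound
  for (nm in names(bp)) {
    r <- cor(bp[[nm]]$values, kern)
    expect_lt(abs(r), 0.1)
  }
})

test_that("session CSV round-trip preserves the traces", {
  cfg <- sim_config(duration_s = 60, stim_interval_s = 30, seed = 4)
  ses <- simulate_session(cfg)
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  p <- read_pupil_csv(file.path(dir, "pupil.csv"))
  expect_equal(p$values, ses$pupil$values, tolerance = 1e-9)
  expect_equal(p$rate_hz, 10)
  e <- read_eeg_csv(file.path(dir, "eeg.csv"))
  expect_equal(e$values, ses$eeg$values, tolerance = 1e-8)
  st <- read_stim_csv(file.path(dir, "stim.csv"))
  expect_equal(st$onset_s, ses$stim_onsets, tolerance = 1e-9)
})
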