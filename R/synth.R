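## Synthetic pupil + EEG sessions with known ground truth.
##
## The generator emulates the statistical structure the analysis assumes:
## a slowly drifting pupil trace carrying transient phasic dilations, and a
## single-channel EEG built from a 1/f-with-knee aperiodic background plus
## band-limited oscillations whose amplitude envelopes are coupled to the
## dilation events with class-specific gains (spontaneous vs. evoked).

#' Canonical EEG band coupling table for the generator
#'
#' One row per canonical band with the oscillation amplitude (standard
#' deviation of the band-limited component, in uV) and the envelope gains
#' applied around spontaneous and evoked dilation events. The default gains
#' encode the arousal signature the pipeline is designed to resolve: power
#' shifting away from the low bands and into the gamma bands around a
#' dilation, with a stronger high-gamma engagement for stimulation-evoked
#' events.
#'
#' @param gain_spontaneous,gain_evoked optional named numeric vectors
#'   (names = band names) overriding individual gains.
#' @return a data.frame with columns `band`, `osc_sd_uv`,
#'   `gain_spontaneous`, `gain_evoked`, `lag_s`.
#' @export
default_band_coupling <- function(gain_spontaneous = NULL, gain_evoked = NULL) {
  bands <- canonical_bands()
  cp <- data.frame(
    band = bands$name,
    osc_sd_uv = c(6, 5, 4, 4, 4, 3.5),
    gain_spontaneous = c(-0.4, -0.3, -0.2, 0.1, 0.3, 0.5),
    gain_evoked = c(-0.4, -0.3, -0.2, 0.1, 0.5, 1.2),
    lag_s = 0,
    stringsAsFactors = FALSE
  )
  for (nm in names(gain_spontaneous)) {
    cp$gain_spontaneous[cp$band == nm] <- gain_spontaneous[[nm]]
  }
  for (nm in names(gain_evoked)) {
    cp$gain_evoked[cp$band == nm] <- gain_evoked[[nm]]
  }
  cp
}

#' Configuration of a synthetic session
#'
#' @param duration_s session length in seconds.
#' @param pupil_rate_hz pupil sampling rate (Hz).
#' @param eeg_rate_hz EEG sampling rate (Hz).
#' @param event_rate_per_s mean rate of spontaneous dilations (1/s). The
#'   inter-event process is a refractory renewal process: a hard minimum
#'   separation `refractory_s` plus an exponential waiting time whose mean is
#'   chosen so the overall mean interval equals `1/event_rate_per_s`.
#' @param refractory_s minimum separation between spontaneous events (s).
#' @param kernel_rise_s,kernel_decay_s time constants of the
#'   difference-of-exponentials dilation kernel (s).
#' @param event_amp_z peak amplitude of a dilation in the raw trace units
#'   (interpreted as z-scale units; must be >= 0).
#' @param slow_noise_sd standard deviation of the slow baseline drift.
#' @param slow_noise_cutoff_hz low-pass cutoff of the drift process (Hz).
#' @param stim_interval_s interval between stimulation onsets (s); `Inf`
#'   disables stimulation (a spontaneous-only session).
#' @param stim_duration_s duration of each stimulation train (s).
#' @param evoked_latency_s latency from stimulation onset to the evoked
#'   pupil peak (s).
#' @param evoked_amp_z peak amplitude of evoked dilations.
#' @param aperiodic_offset,aperiodic_knee,aperiodic_exponent parameters `b`,
#'   `k`, `chi` of the aperiodic EEG background,
#'   `log10 PSD(f) = b - log10(k + f^chi)` (PSD in uV^2/Hz).
#' @param band_coupling coupling table as from [default_band_coupling()];
#'   `NULL` disables all oscillatory bands (pure aperiodic EEG).
#' @param seed master seed for the session.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 600,
                       pupil_rate_hz = 10,
                       eeg_rate_hz = 1000,
                       event_rate_per_s = 1 / 30,
                       refractory_s = 10,
                       kernel_rise_s = 0.5,
                       kernel_decay_s = 2,
                       event_amp_z = 2,
                       slow_noise_sd = 0.3,
                       slow_noise_cutoff_hz = 0.05,
                       stim_interval_s = 30,
                       stim_duration_s = 2,
                       evoked_latency_s = 2.5,
                       evoked_amp_z = event_amp_z,
                       aperiodic_offset = 1.5,
                       aperiodic_knee = 15,
                       aperiodic_exponent = 1.8,
                       band_coupling = default_band_coupling(),
                       seed = 1L) {
  cfg <- list(
    duration_s = duration_s, pupil_rate_hz = pupil_rate_hz,
    eeg_rate_hz = eeg_rate_hz, event_rate_per_s = event_rate_per_s,
    refractory_s = refractory_s, kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s, event_amp_z = event_amp_z,
    slow_noise_sd = slow_noise_sd, slow_noise_cutoff_hz = slow_noise_cutoff_hz,
    stim_interval_s = stim_interval_s, stim_duration_s = stim_duration_s,
    evoked_latency_s = evoked_latency_s, evoked_amp_z = evoked_amp_z,
    aperiodic_offset = aperiodic_offset, aperiodic_knee = aperiodic_knee,
    aperiodic_exponent = aperiodic_exponent, band_coupling = band_coupling,
    seed = as.integer(seed)
  )
  kernel_span <- kernel_rise_s + kernel_decay_s
  assert_that(duration_s > 20 * kernel_span,
              "duration_s must exceed 20 kernel spans")
  assert_that(pupil_rate_hz > 0 && eeg_rate_hz > 0 && event_rate_per_s > 0,
              "rates must be positive")
  assert_that(event_rate_per_s * duration_s >= 1,
              "expected number of events must be at least 1")
  assert_that(aperiodic_exponent >= 0, "aperiodic exponent must be >= 0")
  assert_that(aperiodic_knee >= 0, "aperiodic knee must be >= 0")
  assert_that(event_amp_z >= 0 && evoked_amp_z >= 0,
              "negative event amplitudes are not allowed")
  assert_that(refractory_s * event_rate_per_s < 1,
              "refractory period incompatible with the requested event rate")
  if (!is.null(band_coupling)) {
    assert_that(all(band_coupling$gain_spontaneous >= -1) &&
                  all(band_coupling$gain_evoked >= -1),
                "band gains below -1 would imply negative power")
  }
  structure(cfg, class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %.0f s, pupil %g Hz / EEG %g Hz, seed %d\n",
              x$duration_s, x$pupil_rate_hz, x$eeg_rate_hz, x$seed))
  cat(sprintf("  events: rate 1/%.1f s, amp %.2f z, refractory %.1f s\n",
              1 / x$event_rate_per_s, x$event_amp_z, x$refractory_s))
  if (is.finite(x$stim_interval_s)) {
    cat(sprintf("  stimulation: every %.0f s (%.1f s trains), evoked latency %.1f s\n",
                x$stim_interval_s, x$stim_duration_s, x$evoked_latency_s))
  }
  invisible(x)
}

## Unit-peak dilation kernel: difference of exponentials, shifted so the
## maximum sits at t = 0 with value 1.
dilation_kernel <- function(t, rise_s, decay_s) {
  stopifnot(decay_s > rise_s)
  tpk <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  peak <- exp(-tpk / decay_s) - exp(-tpk / rise_s)
  tt <- t + tpk
  k <- ifelse(tt >= 0, (exp(-tt / decay_s) - exp(-tt / rise_s)) / peak, 0)
  k
}

## Superposition of unit-peak kernels at the event times, scaled per event.
kernel_train <- function(times, event_times, amps, rise_s, decay_s, lag_s = 0) {
  n <- length(times)
  out <- numeric(n)
  if (n < 2L) return(out)
  dt <- times[2] - times[1] # uniform grid
  span <- 12 * decay_s
  for (i in seq_along(event_times)) {
    centre <- event_times[i] + lag_s
    i0 <- max(1L, ceiling((centre - (rise_s + decay_s) - times[1]) / dt) + 1L)
    i1 <- min(n, floor((centre + span - times[1]) / dt) + 1L)
    if (i0 <= i1) {
      sel <- i0:i1
      out[sel] <- out[sel] +
        amps[i] * dilation_kernel(times[sel] - centre, rise_s, decay_s)
    }
  }
  out
}

#' Simulate a pupil trace with planted dilation events
#'
#' The trace is slow coloured noise (white Gaussian noise low-pass filtered
#' at `slow_noise_cutoff_hz` and rescaled to `slow_noise_sd`) plus one
#' unit-peak difference-of-exponentials kernel per event, scaled to
#' `event_amp_z`, so the trace attains exactly the event amplitude at each
#' planted peak (up to noise).
#'
#' @param config a [sim_config()].
#' @param event_times event peak times in seconds, inside `[0, duration_s]`.
#' @param amps optional per-event peak amplitudes (default `event_amp_z`).
#' @return a [pupil_trace()] in raw units.
#' @export
simulate_pupil <- function(config, event_times, amps = NULL) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(all(event_times >= 0 & event_times <= config$duration_s),
              "event times must lie inside [0, duration_s]")
  amps <- amps %||% rep(config$event_amp_z, length(event_times))
  assert_that(all(amps >= 0), "negative event amplitudes are not allowed")
  n <- round(config$duration_s * config$pupil_rate_hz)
  times <- (seq_len(n) - 1) / config$pupil_rate_hz
  sig <- kernel_train(times, event_times, amps,
                      config$kernel_rise_s, config$kernel_decay_s)
  if (config$slow_noise_sd > 0) {
    noise <- withr::with_seed(child_seed(config$seed, 1L), rnorm(n))
    lp <- signal::butter(4, config$slow_noise_cutoff_hz / (config$pupil_rate_hz / 2),
                         type = "low")
    noise <- zero_phase(lp, noise, pad = n - 1L)
    noise <- noise / sd(noise) * config$slow_noise_sd
    sig <- sig + noise
  }
  pupil_trace(sig, rate_hz = config$pupil_rate_hz, t0_s = 0, state = "raw")
}

#' Simulate an EEG trace with event-coupled band-limited oscillations
#'
#' The trace is the sum of (i) an aperiodic background whose expected
#' one-sided periodogram follows `log10 PSD(f) = b - log10(k + f^chi)`,
#' synthesized by spectral shaping of complex Gaussian coefficients, and
#' (ii) per band, white noise band-pass filtered to the band and amplitude
#' modulated by the envelope `1 + gain_label * kernel(t - peak + lag)`,
#' where the kernel is the same unit-peak dilation kernel used for the
#' pupil and the gain depends on the event class.
#'
#' @param config a [sim_config()].
#' @param event_times event peak times (s).
#' @param labels class per event, `"spontaneous"` or `"evoked"`.
#' @return an [eeg_trace()] in microvolts (state `"raw"`).
#' @export
simulate_eeg <- function(config, event_times, labels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  labels <- labels %||% rep("spontaneous", length(event_times))
  assert_that(length(labels) == length(event_times),
              "labels must align with event_times")
  assert_that(all(labels %in% c("spontaneous", "evoked")),
              "labels must be 'spontaneous' or 'evoked'")
  fs <- config$eeg_rate_hz
  n <- round(config$duration_s * fs)
  times <- (seq_len(n) - 1) / fs

  x <- aperiodic_background(n, fs, config$aperiodic_offset,
                            config$aperiodic_knee, config$aperiodic_exponent,
                            seed = child_seed(config$seed, 2L))

  cp <- config$band_coupling
  if (!is.null(cp) && nrow(cp)) {
    bands <- canonical_bands()
    for (i in seq_len(nrow(cp))) {
      bd <- bands[bands$name == cp$band[i], ]
      if (!nrow(bd)) next
      carrier <- band_limited_noise(n, fs, bd$f_lo, bd$f_hi,
                                    seed = child_seed(config$seed, 10L + i))
      carrier <- carrier * cp$osc_sd_uv[i]
      if (length(event_times)) {
        gains <- ifelse(labels == "evoked", cp$gain_evoked[i], cp$gain_spontaneous[i])
        env <- 1 + kernel_train(times, event_times, gains,
                                config$kernel_rise_s, config$kernel_decay_s,
                                lag_s = cp$lag_s[i])
        env[env < 0] <- 0
        carrier <- carrier * env
      }
      x <- x + carrier
    }
  }
  eeg_trace(x, rate_hz = fs, t0_s = 0, state = "raw")
}

## Real signal whose expected one-sided periodogram equals
## 10^b / (k + f^chi): Hermitian spectrum with complex Gaussian coefficients
## of matching variance, inverse FFT.
aperiodic_background <- function(n, fs, b, k, chi, seed) {
  nyq <- n %/% 2
  f <- (1:nyq) * fs / n
  s <- 10^b / (k + f^chi) # target one-sided PSD (uV^2/Hz)
  amp <- sqrt(s * fs * n / 2)
  withr::with_seed(seed, {
    re <- rnorm(nyq)
    im <- rnorm(nyq)
  })
  pos <- complex(real = re, imaginary = im) * amp / sqrt(2)
  if (n %% 2 == 0) pos[nyq] <- complex(real = re[nyq] * amp[nyq], imaginary = 0)
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2:(nyq + 1)] <- pos
  if (n %% 2 == 0) {
    spec[(nyq + 2):n] <- Conj(rev(pos[1:(nyq - 1)]))
  } else {
    spec[(nyq + 2):n] <- Conj(rev(pos))
  }
  Re(fft(spec, inverse = TRUE)) / n
}

## Unit-variance Gaussian noise strictly band-limited to [f_lo, f_hi],
## synthesized in the frequency domain (complex Gaussian coefficients inside
## the band, zero outside). Narrow low-frequency bands make time-domain IIR
## band-passes numerically fragile at 1000 Hz; the spectral construction is
## exact and stable.
band_limited_noise <- function(n, fs, f_lo, f_hi, seed) {
  nyq <- n %/% 2
  f <- (1:nyq) * fs / n
  inband <- f >= f_lo & f <= f_hi
  withr::with_seed(seed, {
    re <- rnorm(nyq)
    im <- rnorm(nyq)
  })
  pos <- complex(real = re, imaginary = im) * inband
  if (n %% 2 == 0) pos[nyq] <- complex(real = re[nyq] * inband[nyq], imaginary = 0)
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2:(nyq + 1)] <- pos
  if (n %% 2 == 0) {
    spec[(nyq + 2):n] <- Conj(rev(pos[1:(nyq - 1)]))
  } else {
    spec[(nyq + 2):n] <- Conj(rev(pos))
  }
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate a complete session (pupil + EEG + ground truth)
#'
#' Stimulation onsets are laid every `stim_interval_s` seconds starting at a
#' random phase in `(0, stim_interval_s]`; one evoked event is planted
#' `evoked_latency_s` after each onset. Spontaneous event times are drawn
#' from the refractory renewal process and thinned so that none falls within
#' 10 s of a stimulation onset (or inside the margins where the metric
#' windows would leave the trace).
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_session`: list with `pupil`, `eeg`,
#'   `truth_events` (data.frame `peak_time_s`, `label`), `stim_onsets`,
#'   `config`.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dur <- config$duration_s
  margin <- 10

  stim_onsets <- numeric(0)
  if (is.finite(config$stim_interval_s)) {
    first <- withr::with_seed(child_seed(config$seed, 3L),
                              runif(1, 0, config$stim_interval_s))
    stim_onsets <- seq(first, dur - margin, by = config$stim_interval_s)
  }
  evoked <- stim_onsets + config$evoked_latency_s

  spont <- withr::with_seed(child_seed(config$seed, 4L), {
    mean_iv <- 1 / config$event_rate_per_s
    exp_mean <- mean_iv - config$refractory_s
    t <- margin
    out <- numeric(0)
    repeat {
      t <- t + config$refractory_s + stats::rexp(1, rate = 1 / exp_mean)
      if (t > dur - margin) break
      out <- c(out, t)
    }
    out
  })
  if (length(stim_onsets)) {
    near_stim <- vapply(spont, function(t) any(abs(t - stim_onsets) < 10), logical(1))
    spont <- spont[!near_stim]
  }

  ev <- data.frame(
    peak_time_s = c(spont, evoked),
    label = c(rep("spontaneous", length(spont)), rep("evoked", length(evoked))),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$peak_time_s), , drop = FALSE]
  rownames(ev) <- NULL

  amps <- ifelse(ev$label == "evoked", config$evoked_amp_z, config$event_amp_z)
  pupil <- simulate_pupil(config, ev$peak_time_s, amps)
  eeg <- simulate_eeg(config, ev$peak_time_s, ev$label)

  structure(list(pupil = pupil, eeg = eeg, truth_events = ev,
                 stim_onsets = stim_onsets, config = config),
            class = "sim_session")
}

#' @exportS3Method base::print
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %.0f s: %d spontaneous + %d evoked events, %d stim onsets\n",
              x$config$duration_s,
              sum(x$truth_events$label == "spontaneous"),
              sum(x$truth_events$label == "evoked"),
              length(x$stim_onsets)))
  invisible(x)
}
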