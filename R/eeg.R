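## EEG filtering, windowed PSD estimation and band power on the pupil grid.

#' Construct an EEG trace
#' @param values samples in microvolts.
#' @param rate_hz sampling rate in Hz (1000 for the standard pipeline).
#' @param t0_s time of the first sample (s).
#' @param state `"raw"` or `"filtered"`.
#' @return an object of class `eeg_trace`.
#' @export
eeg_trace <- function(values, rate_hz = 1000, t0_s = 0, state = "raw") {
  assert_that(is.numeric(values) && all(is.finite(values)),
              "EEG values must be finite numerics")
  structure(list(values = as.numeric(values), rate_hz = rate_hz,
                 t0_s = t0_s, state = state),
            class = "eeg_trace")
}

#' @exportS3Method base::print
print.eeg_trace <- function(x, ...) {
  cat(sprintf("<eeg_trace> %d samples @ %g Hz (%.1f s), state: %s\n",
              length(x$values), x$rate_hz, length(x$values) / x$rate_hz,
              x$state))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-12, beta 12-30, low gamma 30-55 and high
#' gamma 65-100 Hz. The 55-65 Hz gap around the mains notch belongs to no
#' band.
#'
#' @return data.frame with columns `name`, `f_lo`, `f_hi`.
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    f_lo = c(1, 4, 8, 12, 30, 65),
    f_hi = c(4, 8, 12, 30, 55, 100),
    stringsAsFactors = FALSE
  )
}

#' Filter a raw EEG trace
#'
#' Zero-phase 6th-order Butterworth low-pass at 100 Hz followed by a
#' zero-phase 60 Hz notch (2nd-order IIR, quality factor 30).
#'
#' @param raw an [eeg_trace()] at 1000 Hz.
#' @param lowpass_hz low-pass cutoff (Hz).
#' @param notch_hz mains frequency to reject (Hz); `NA` disables the notch.
#' @return the filtered [eeg_trace()] (state `"filtered"`).
#' @export
preprocess_eeg <- function(raw, lowpass_hz = 100, notch_hz = 60) {
  stopifnot(inherits(raw, "eeg_trace"))
  fs <- raw$rate_hz
  assert_that(length(raw$values) >= 5 * fs, "EEG traces shorter than 5 s rejected")
  x <- zero_phase(eeg_lowpass(fs, lowpass_hz), raw$values, pad = round(fs))
  if (!is.na(notch_hz)) {
    x <- zero_phase(notch_filter(notch_hz, fs, q = 30), x, pad = round(fs))
  }
  eeg_trace(x, rate_hz = fs, t0_s = raw$t0_s, state = "filtered")
}

## One-sided periodogram with density normalization (rectangular taper):
## psd integrates (sum * df) to the mean squared signal. DC and (for even n)
## Nyquist bins are not doubled.
periodogram <- function(x, fs, taper = c("rect", "hann")) {
  taper <- match.arg(taper)
  n <- length(x)
  scale_u <- 1
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    scale_u <- mean(w^2)
    x <- x * w
  }
  X <- fft(x)
  nyq <- n %/% 2
  p <- Mod(X[1:(nyq + 1)])^2 / (fs * n * scale_u)
  mult <- rep(2, nyq + 1)
  mult[1] <- 1
  if (n %% 2 == 0) mult[nyq + 1] <- 1
  list(freqs = (0:nyq) * fs / n, psd = p * mult)
}

#' Periodogram of one analysis window
#'
#' One-sided FFT periodogram with density normalization on the 1 Hz grid
#' 0-500 Hz. Parseval-consistent: `sum(psd) * df` equals the mean squared
#' signal (the DC and Nyquist bins are not doubled).
#'
#' @param samples exactly 1000 EEG samples (one 1 s window at 1000 Hz).
#' @param rate_hz sampling rate (Hz).
#' @param taper `"rect"` (default, plain FFT periodogram) or `"hann"`.
#' @return an object of class `spectrum_estimate`: list with `freqs`, `psd`,
#'   `window_span_s`.
#' @export
window_psd <- function(samples, rate_hz = 1000, taper = "rect") {
  assert_that(length(samples) == 1000,
              "contract error: window_psd expects exactly 1000 samples")
  pg <- periodogram(samples, rate_hz, taper)
  spectrum_estimate(pg$freqs, pg$psd, window_span_s = length(samples) / rate_hz)
}

#' Construct a spectrum estimate
#' @param freqs frequency grid (Hz), strictly increasing.
#' @param psd power spectral density (uV^2/Hz), non-negative.
#' @param window_span_s span of the analysis window (s).
#' @return an object of class `spectrum_estimate`.
#' @export
spectrum_estimate <- function(freqs, psd, window_span_s) {
  assert_that(all(diff(freqs) > 0), "freqs must be strictly increasing")
  assert_that(all(psd >= 0), "psd must be non-negative")
  structure(list(freqs = freqs, psd = psd, window_span_s = window_span_s),
            class = "spectrum_estimate")
}

#' Band power as the area under the PSD curve
#'
#' Trapezoidal integral of the PSD over `[f_lo, f_hi]` on the spectrum's
#' native grid, endpoints included.
#'
#' @param spec a [spectrum_estimate()].
#' @param band one row of [canonical_bands()] (or any list with `f_lo`,
#'   `f_hi`).
#' @return the band AUC (uV^2-scale power).
#' @export
band_auc <- function(spec, band) {
  sel <- spec$freqs >= band$f_lo & spec$freqs <= band$f_hi
  assert_that(sum(sel) >= 2, "band has no overlap with the spectrum grid")
  trapz(spec$freqs[sel], spec$psd[sel])
}

#' Sliding-window band power on the 100 Hz pupil grid
#'
#' Segments the filtered EEG into 1 s windows (1000 samples) advanced in
#' steps of 10 samples (10 ms), computes each window's periodogram and
#' integrates it over each requested band. The resulting series are sampled
#' at 100 Hz and timestamped at the window centres, so they share the pupil
#' trace's 0.01 s grid. For `N` EEG samples the series has
#' `(N - 1000) / 10 + 1` points.
#'
#' @param eeg a filtered [eeg_trace()] at 1000 Hz.
#' @param bands data.frame of band definitions (default [canonical_bands()]).
#' @param window_len window length in samples.
#' @param step step in samples.
#' @return named list of `band_power_series` objects (one per band), each a
#'   list with `band`, `values`, `rate_hz` (100), `t0_s`.
#' @export
sliding_band_power <- function(eeg, bands = canonical_bands(),
                               window_len = 1000, step = 10) {
  stopifnot(inherits(eeg, "eeg_trace"))
  fs <- eeg$rate_hz
  x <- eeg$values
  n <- length(x)
  assert_that(n >= window_len, "EEG shorter than one analysis window")
  n_win <- (n - window_len) %/% step + 1L

  # real DFT restricted to the 1..(fs/window_len)*k Hz bins covering the
  # requested bands; identical to the per-window FFT periodogram on those
  # bins, but evaluated as two matrix products per chunk.
  df <- fs / window_len
  f_max_bin <- ceiling(max(bands$f_hi) / df)
  fr <- seq_len(f_max_bin) # bin indices (frequency = fr * df)
  tt <- 0:(window_len - 1)
  ang <- 2 * pi * outer(fr, tt) / window_len
  basis <- rbind(cos(ang), sin(ang))
  freqs <- fr * df
  # per-band trapezoid weights on the restricted grid
  wts <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- which(freqs >= bands$f_lo[i] & freqs <= bands$f_hi[i])
    assert_that(length(sel) >= 2, "band has no overlap with the spectrum grid")
    w <- numeric(length(freqs))
    dfs <- diff(freqs[sel])
    w[sel[-length(sel)]] <- w[sel[-length(sel)]] + dfs / 2
    w[sel[-1]] <- w[sel[-1]] + dfs / 2
    w
  })

  out_vals <- matrix(NA_real_, nrow = n_win, ncol = nrow(bands))
  chunk <- 4096L
  idx_base <- outer(0:(window_len - 1L), 0:(chunk - 1L) * step, "+") + 1L
  for (s0 in seq(1L, n_win, by = chunk)) {
    m <- min(chunk, n_win - s0 + 1L)
    idx <- if (m == chunk) idx_base + (s0 - 1L) * step else
      outer(0:(window_len - 1L), (s0 - 1L + 0:(m - 1L)) * step, "+") + 1L
    M <- matrix(x[idx], nrow = window_len)
    G <- basis %*% M
    P <- (G[seq_len(f_max_bin), , drop = FALSE]^2 +
            G[f_max_bin + seq_len(f_max_bin), , drop = FALSE]^2) *
      (2 / (fs * window_len))
    for (b in seq_len(nrow(bands))) {
      out_vals[s0:(s0 + m - 1L), b] <- crossprod(P, wts[[b]])
    }
  }

  t0_series <- eeg$t0_s + (window_len / 2) / fs # centre-of-window timestamps
  rate_out <- fs / step
  res <- lapply(seq_len(nrow(bands)), function(b) {
    structure(list(band = bands[b, , drop = FALSE],
                   values = out_vals[, b],
                   rate_hz = rate_out, t0_s = t0_series),
              class = "band_power_series")
  })
  names(res) <- bands$name
  res
}

#' @exportS3Method base::print
print.band_power_series <- function(x, ...) {
  cat(sprintf("<band_power_series> %s (%g-%g Hz): %d points @ %g Hz from t=%g s\n",
              x$band$name, x$band$f_lo, x$band$f_hi, length(x$values),
              x$rate_hz, x$t0_s))
  invisible(x)
}

#' Session-level normalized PSD from random 2 s segments
#'
#' Draws `n_segments` non-overlapping 2 s segments (on a 2 s grid, seeded),
#' averages their periodograms, and divides by the total 1-100 Hz power so
#' the normalized spectrum integrates to 1 over that range. Per-band
#' normalized power is each band's fraction of the total; because the
#' 0-1 Hz and 55-65 Hz gaps are excluded from every band, the six fractions
#' sum to less than 1.
#'
#' @param eeg a filtered [eeg_trace()].
#' @param n_segments number of 2 s segments to draw.
#' @param segment_s segment length (s).
#' @param seed RNG seed for the segment draw.
#' @param bands band definitions.
#' @return list with `spectrum` (normalized [spectrum_estimate()]),
#'   `band_fractions` (named numeric), `total_power` (the 1-100 Hz AUC of
#'   the raw averaged PSD) and `n_segments`.
#' @export
session_normalized_psd <- function(eeg, n_segments = 100, segment_s = 2,
                                   seed = 1L, bands = canonical_bands()) {
  stopifnot(inherits(eeg, "eeg_trace"))
  fs <- eeg$rate_hz
  seg_len <- round(segment_s * fs)
  n_slots <- length(eeg$values) %/% seg_len
  assert_that(n_slots >= n_segments,
              "insufficient data for the requested number of segments")
  slots <- withr::with_seed(seed, sample.int(n_slots, n_segments))
  acc <- NULL
  for (s in slots) {
    pg <- periodogram(eeg$values[((s - 1) * seg_len + 1):(s * seg_len)], fs)
    acc <- if (is.null(acc)) pg$psd else acc + pg$psd
  }
  psd <- acc / n_segments
  spec <- spectrum_estimate(pg$freqs, psd, window_span_s = segment_s)
  total <- band_auc(spec, list(f_lo = 1, f_hi = 100))
  norm_spec <- spectrum_estimate(pg$freqs, psd / total, window_span_s = segment_s)
  fr <- vapply(seq_len(nrow(bands)), function(i) {
    band_auc(norm_spec, bands[i, ])
  }, numeric(1))
  names(fr) <- bands$name
  list(spectrum = norm_spec, band_fractions = fr, total_power = total,
       n_segments = n_segments)
}
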