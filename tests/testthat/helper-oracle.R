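# Independent oracles and shared fixtures.

# Brute-force dilation detector: literally evaluates the three printed
# criteria at every 0.01 s offset (quiet 2 s pre-window, supra-threshold
# first local maximum, return below threshold within 6 s), then replays the
# sequential acceptance rule (skip windows starting before the previous
# event's offset). Shares no code with the package's sliding detector.
brute_force_detect <- function(x, fs = 100, thr = 0.5, window_s = 10,
                               quiet_s = 2, return_s = 6, halfspan_s = 6) {
  n <- length(x)
  wlen <- round(window_s * fs)
  blen <- round(quiet_s * fs)
  rlen <- round(return_s * fs)
  hspan <- round(halfspan_s * fs)
  starts <- seq_len(n - wlen + 1L)

  # criterion 1 at every offset: first quiet_s stay continuously below thr
  quiet_ok <- zoo::rollmax(x, blen, align = "left") < thr
  quiet_ok <- quiet_ok[starts]

  # candidate peaks anywhere: supra-threshold samples that are local maxima
  # (plateaus resolve to their first sample); interior samples only
  is_lm <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  cand <- which(is_lm & x > thr)

  # criterion 3 per candidate: next sub-threshold sample within return_s
  below_idx <- which(x < thr)
  nxt_below <- below_idx[findInterval(cand, below_idx) + 1L]
  return_ok <- !is.na(nxt_below) & (nxt_below - cand) <= rlen

  # per offset: the first candidate inside the window (the first detected
  # peak); the window yields an event only if that candidate returns in time
  pos <- findInterval(starts - 1L, cand) + 1L
  pk_win <- ifelse(pos <= length(cand), cand[pos], NA_integer_)
  in_win <- !is.na(pk_win) & pk_win <= starts + wlen - 1L
  yields <- quiet_ok & in_win & ifelse(in_win, return_ok[pos], FALSE)

  # sequential acceptance: earliest yielding window wins, search resumes at
  # the event offset (first sub-threshold sample after the peak)
  peaks <- integer(0)
  dropped <- 0L
  ptr <- 1L
  for (i in which(yields)) {
    if (i < ptr) next
    pk <- pk_win[i]
    if (pk - hspan >= 1L && pk + hspan - 1L <= n) {
      peaks <- c(peaks, pk)
    } else {
      dropped <- dropped + 1L
    }
    ptr <- nxt_below[pos[i]]
  }
  list(peak_index = peaks, dropped = dropped)
}

# Direct windowed-mean oracle for event metrics (independent loop).
brute_force_metrics <- function(x, fs, t0, peak_time, win) {
  times <- t0 + (seq_along(x) - 1) / fs
  sel <- times >= peak_time + win[1] - 1e-9 & times < peak_time + win[2] - 1e-9
  mean(x[sel])
}

# Greedy one-to-one matching of detected peaks to planted peaks.
match_events <- function(detected_s, truth_s, tol_s = 1) {
  used <- rep(FALSE, length(truth_s))
  tp <- 0L
  for (d in detected_s) {
    j <- which(!used & abs(truth_s - d) < tol_s)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

# Preprocessed-state pupil trace built directly from values (for detector
# unit tests that construct the 100 Hz signal analytically).
as_preprocessed_trace <- function(values, rate_hz = 100, t0_s = 0) {
  pupil_trace(values, rate_hz = rate_hz, t0_s = t0_s,
              state = c("raw", "blink_interpolated", "lowpassed", "zscored",
                        "upsampled", "highpassed"))
}

# Random pupil-like test signal: slow noise plus a few planted kernels,
# z-scored; used for detector/oracle equivalence sweeps.
random_detector_trace <- function(seed, duration_s = 600, fs = 100) {
  withr::with_seed(seed, {
    n <- duration_s * fs
    t <- (0:(n - 1)) / fs
    lp <- signal::butter(2, 0.25 / (fs / 2), type = "low")
    noise <- signal::filtfilt(lp, rnorm(n))
    noise <- noise / sd(noise) * runif(1, 0.2, 0.5)
    n_ev <- rpois(1, duration_s / 40)
    x <- noise
    if (n_ev > 0) {
      at <- runif(n_ev, 8, duration_s - 8)
      amp <- runif(n_ev, 0.5, 3)
      for (k in seq_len(n_ev)) {
        x <- x + amp[k] * exp(-(t - at[k])^2 / (2 * runif(1, 0.3, 1.5)^2))
      }
    }
    as_preprocessed_trace((x - mean(x)) / sd(x), rate_hz = fs)
  })
}
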