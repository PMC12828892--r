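## Pupil preprocessing and phasic dilation detection.

#' Construct a pupil trace
#'
#' @param values pupil size samples (raw units or z-units).
#' @param rate_hz sampling rate in Hz.
#' @param t0_s time of the first sample in seconds.
#' @param state character vector recording the preprocessing steps applied,
#'   a subset of `c("raw", "blink_interpolated", "lowpassed", "zscored",
#'   "upsampled", "highpassed")`.
#' @return an object of class `pupil_trace`.
#' @export
pupil_trace <- function(values, rate_hz, t0_s = 0, state = "raw") {
  assert_that(is.numeric(values) && length(values) > 0, "values must be numeric")
  structure(list(values = as.numeric(values), rate_hz = rate_hz,
                 t0_s = t0_s, state = state),
            class = "pupil_trace")
}

#' @exportS3Method base::print
print.pupil_trace <- function(x, ...) {
  cat(sprintf("<pupil_trace> %d samples @ %g Hz (%.1f s), state: %s\n",
              length(x$values), x$rate_hz, length(x$values) / x$rate_hz,
              paste(x$state, collapse = "+")))
  invisible(x)
}

#' Detection configuration for phasic pupil dilations
#'
#' Defaults follow the sliding-window protocol: 10 s windows advanced in
#' 0.01 s steps over the 100 Hz preprocessed trace; a window qualifies when
#' its first 2 s stay continuously below the z-score threshold; the first
#' supra-threshold local maximum in the window is the candidate peak, and
#' the event is accepted only if the trace returns below threshold within
#' 6 s of the peak. Baseline is the mean over [-6, -4) s before the peak,
#' amplitude the mean over [-2.5, 2.5) s around it minus baseline.
#'
#' @param threshold_sd detection threshold in z-units (0.5 by default;
#'   0.65 and 1.0 are the standard alternates).
#' @param window_s sliding-window length (s).
#' @param baseline_span_s length of the quiet pre-window (s).
#' @param return_within_s maximum time to return below threshold after the
#'   peak (s).
#' @param step_s sliding step (s).
#' @param baseline_window_s baseline metric window relative to the peak (s).
#' @param amplitude_window_s amplitude metric window relative to the peak (s).
#' @param align_halfspan_s half-width of the peak-aligned analysis window (s).
#' @param lowpass_hz pupil low-pass cutoff applied before z-scoring (Hz).
#' @param highpass_hz drift-removal high-pass cutoff applied after
#'   upsampling (Hz).
#' @param out_rate_hz target rate of the upsampled trace (Hz).
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(threshold_sd = 0.5,
                             window_s = 10,
                             baseline_span_s = 2,
                             return_within_s = 6,
                             step_s = 0.01,
                             baseline_window_s = c(-6, -4),
                             amplitude_window_s = c(-2.5, 2.5),
                             align_halfspan_s = 6,
                             lowpass_hz = 3.5,
                             highpass_hz = 0.1,
                             out_rate_hz = 100) {
  assert_that(threshold_sd > 0, "threshold_sd must be positive")
  assert_that(baseline_span_s < window_s, "baseline span must fit in the window")
  assert_that(return_within_s < window_s, "return window must fit in the window")
  structure(list(threshold_sd = threshold_sd, window_s = window_s,
                 baseline_span_s = baseline_span_s,
                 return_within_s = return_within_s, step_s = step_s,
                 baseline_window_s = baseline_window_s,
                 amplitude_window_s = amplitude_window_s,
                 align_halfspan_s = align_halfspan_s,
                 lowpass_hz = lowpass_hz, highpass_hz = highpass_hz,
                 out_rate_hz = out_rate_hz),
            class = "detection_config")
}

#' Preprocess a raw pupil trace
#'
#' Steps, in order: (1) linear interpolation across blink intervals using
#' the samples just before and after each blink; (2) zero-phase 4th-order
#' low-pass at 3.5 Hz; (3) z-scoring with the whole-session mean and SD;
#' (4) cubic-spline upsampling from 10 to 100 Hz; (5) zero-phase 4th-order
#' high-pass at 0.1 Hz to remove slow drift. The output carries the list of
#' applied steps in its `state`. The upsampled trace has exactly
#' `10 * length(input)` samples: the output grid starts at the first input
#' sample and extends one input sampling interval short of the end-plus-one
#' sample (the spline extrapolates over the final 0.09 s).
#'
#' @param raw a [pupil_trace()] at the native (10 Hz) rate.
#' @param blink_intervals optional two-column matrix or data.frame of blink
#'   start/end times in seconds.
#' @param cfg a [detection_config()].
#' @return a preprocessed [pupil_trace()] at `cfg$out_rate_hz`.
#' @export
preprocess_pupil <- function(raw, blink_intervals = NULL, cfg = detection_config()) {
  stopifnot(inherits(raw, "pupil_trace"))
  n <- length(raw$values)
  dur <- n / raw$rate_hz
  assert_that(dur >= 20, "trace shorter than 20 s rejected: filters unstable")
  x <- raw$values
  t_in <- trace_times(raw)

  if (!is.null(blink_intervals) && NROW(blink_intervals) > 0) {
    bi <- as.matrix(blink_intervals)
    assert_that(ncol(bi) == 2, "blink_intervals needs start/end columns")
    assert_that(all(bi[, 1] < bi[, 2]), "blink intervals must have start < end")
    assert_that(all(bi >= t_in[1] & bi <= t_in[n]),
                "blink intervals must lie inside the trace span")
    covered <- sum(bi[, 2] - bi[, 1])
    assert_that(covered <= 0.5 * dur,
                "blink intervals covering more than half the trace rejected")
    for (i in seq_len(nrow(bi))) {
      inside <- which(t_in >= bi[i, 1] & t_in <= bi[i, 2])
      if (!length(inside)) next
      pre <- min(inside) - 1L
      post <- max(inside) + 1L
      assert_that(pre >= 1L && post <= n,
                  "blink interval touches the trace boundary")
      x[inside] <- x[pre] +
        (x[post] - x[pre]) * (t_in[inside] - t_in[pre]) / (t_in[post] - t_in[pre])
    }
  }
  assert_that(all(is.finite(x)), "non-finite pupil values after blink interpolation")

  assert_that(sd(x) > 1e-12 * (abs(mean(x)) + 1),
              "degenerate variance: constant pupil trace cannot be z-scored")
  x <- zero_phase(pupil_lowpass(raw$rate_hz, cfg$lowpass_hz), x,
                  pad = round(5 * raw$rate_hz))

  s <- sd(x)
  assert_that(s > 1e-12, "degenerate variance: constant pupil trace cannot be z-scored")
  x <- (x - mean(x)) / s

  up <- cfg$out_rate_hz / raw$rate_hz
  n_out <- round(n * up)
  t_out <- raw$t0_s + (seq_len(n_out) - 1) / cfg$out_rate_hz
  x <- spline(t_in, x, xout = t_out, method = "fmm")$y

  x <- zero_phase(pupil_highpass(cfg$out_rate_hz, cfg$highpass_hz), x,
                  pad = round(60 * cfg$out_rate_hz))

  pupil_trace(x, rate_hz = cfg$out_rate_hz, t0_s = raw$t0_s,
              state = c("raw", "blink_interpolated", "lowpassed", "zscored",
                        "upsampled", "highpassed"))
}

## Events container: data.frame with class "dilation_events"
dilation_events <- function(peak_time_s = numeric(0), peak_index = integer(0),
                            label = character(0), baseline_z = numeric(0),
                            amplitude_z = numeric(0),
                            onset_start_s = numeric(0), onset_end_s = numeric(0),
                            dropped = 0L) {
  ev <- data.frame(peak_time_s = peak_time_s, peak_index = peak_index,
                   label = label, baseline_z = baseline_z,
                   amplitude_z = amplitude_z, onset_start_s = onset_start_s,
                   onset_end_s = onset_end_s, stringsAsFactors = FALSE)
  attr(ev, "dropped") <- dropped
  class(ev) <- c("dilation_events", "data.frame")
  ev
}

check_detect_contract <- function(trace, cfg) {
  stopifnot(inherits(trace, "pupil_trace"))
  assert_that(trace$rate_hz == cfg$out_rate_hz,
              sprintf("contract error: trace must be at %g Hz", cfg$out_rate_hz))
  needed <- c("zscored", "upsampled", "highpassed")
  assert_that(all(needed %in% trace$state),
              "contract error: trace must be z-scored, upsampled and high-passed")
}

## First index j in `cand` (sorted supra-threshold sample indices) that is a
## local maximum of x; plateau ties resolve to the earliest plateau sample
## (x[j] > x[j-1] and x[j] >= x[j+1]). Boundary samples are never peaks.
first_local_max <- function(x, cand) {
  n <- length(x)
  for (j in cand) {
    if (j <= 1L || j >= n) next
    if (x[j] > x[j - 1L] && x[j] >= x[j + 1L]) return(j)
  }
  NA_integer_
}

#' Detect spontaneous phasic pupil dilations
#'
#' Slides a `window_s` window through the preprocessed trace in `step_s`
#' steps. A window qualifies when every sample of its first
#' `baseline_span_s` seconds is strictly below `threshold_sd`. Within a
#' qualifying window, samples exceeding the threshold are candidate peak
#' regions; the first local maximum among them is the dilation peak, and the
#' event is accepted only if the trace falls back below the threshold within
#' `return_within_s` seconds after the peak. The search then resumes at the
#' event offset (the first sub-threshold sample after the peak). Events
#' whose baseline/amplitude windows (+/- 6 s) would leave the trace are
#' dropped and counted in the `dropped` attribute of the result.
#'
#' @param trace a preprocessed [pupil_trace()] (z-scored, upsampled,
#'   high-passed, 100 Hz).
#' @param cfg a [detection_config()].
#' @return a `dilation_events` data.frame (label `"spontaneous"`).
#' @export
detect_spontaneous_dilations <- function(trace, cfg = detection_config()) {
  check_detect_contract(trace, cfg)
  x <- trace$values
  n <- length(x)
  fs <- trace$rate_hz
  thr <- cfg$threshold_sd
  wlen <- round(cfg$window_s * fs)
  blen <- round(cfg$baseline_span_s * fs)
  rlen <- round(cfg$return_within_s * fs)
  hspan <- round(cfg$align_halfspan_s * fs)

  below <- x < thr
  cb <- c(0, cumsum(below)) # cb[i+1]-cb[j] = count below in j..i (1-based)
  supra_idx <- which(x > thr)

  peaks <- integer(0)
  onsets <- integer(0)
  dropped <- 0L
  i <- 1L
  last_start <- n - wlen + 1L
  while (i <= last_start) {
    # first `blen` samples continuously below threshold?
    if (cb[i + blen] - cb[i] < blen) {
      # jump past the last supra/equal sample inside the quiet span
      bad <- which(!below[i:(i + blen - 1L)])
      i <- i + max(bad)
      next
    }
    # candidate supra-threshold samples within the window
    lo <- findInterval(i - 1L, supra_idx) + 1L
    if (lo > length(supra_idx) || supra_idx[lo] > i + wlen - 1L) {
      # no supra sample in this window: jump until one enters on the right
      nxt <- if (lo <= length(supra_idx)) supra_idx[lo] else NA_integer_
      i <- if (is.na(nxt)) last_start + 1L else max(i + 1L, nxt - wlen + 1L)
      next
    }
    hi <- findInterval(i + wlen - 1L, supra_idx)
    cand <- supra_idx[lo:hi]
    pk <- first_local_max(x, cand)
    if (is.na(pk)) {
      i <- i + 1L
      next
    }
    # return below threshold within return_within_s after the peak
    tail_end <- min(n, pk + rlen)
    off_rel <- which(below[(pk + 1L):tail_end])[1]
    if (pk >= n || is.na(off_rel)) {
      i <- i + 1L
      next
    }
    offset <- pk + off_rel
    if (pk - hspan >= 1L && pk + hspan - 1L <= n) {
      peaks <- c(peaks, pk)
      onsets <- c(onsets, i)
    } else {
      dropped <- dropped + 1L
    }
    i <- offset
  }

  if (!length(peaks)) {
    return(dilation_events(dropped = dropped))
  }
  met <- vapply(peaks, function(pk) {
    compute_event_metrics(trace, trace$t0_s + (pk - 1) / fs, cfg)
  }, numeric(2))
  dilation_events(
    peak_time_s = trace$t0_s + (peaks - 1) / fs,
    peak_index = peaks,
    label = rep("spontaneous", length(peaks)),
    baseline_z = met[1, ],
    amplitude_z = met[2, ],
    onset_start_s = trace$t0_s + (onsets - 1) / fs,
    onset_end_s = trace$t0_s + (onsets - 1) / fs + cfg$window_s,
    dropped = dropped
  )
}

#' Locate stimulation-evoked dilation peaks
#'
#' For each stimulation onset the evoked peak is the maximum of the trace
#' within `(onset, onset + search_span_s]`; overlapping search windows are
#' truncated at the next onset (with a warning). Ties resolve to the
#' earliest sample. Metrics are computed exactly as for spontaneous events;
#' trials whose metric windows leave the trace are dropped and counted.
#'
#' @param trace a preprocessed [pupil_trace()].
#' @param stim_onsets stimulation onset times (s).
#' @param search_span_s post-onset search span (s).
#' @param cfg a [detection_config()].
#' @return a `dilation_events` data.frame (label `"evoked"`).
#' @export
locate_evoked_peaks <- function(trace, stim_onsets, search_span_s = 6,
                                cfg = detection_config()) {
  check_detect_contract(trace, cfg)
  x <- trace$values
  n <- length(x)
  fs <- trace$rate_hz
  hspan <- round(cfg$align_halfspan_s * fs)
  t_end <- trace$t0_s + (n - 1) / fs
  stim_onsets <- sort(stim_onsets)
  assert_that(all(stim_onsets >= trace$t0_s & stim_onsets <= t_end),
              "stimulation onsets must lie inside the trace span")
  if (length(stim_onsets) > 1 &&
      any(diff(stim_onsets) < search_span_s)) {
    warning("overlapping evoked search windows truncated at the next onset")
  }
  peaks <- integer(0)
  dropped <- 0L
  for (idx in seq_along(stim_onsets)) {
    on <- stim_onsets[idx]
    span_end <- on + search_span_s
    if (idx < length(stim_onsets)) span_end <- min(span_end, stim_onsets[idx + 1])
    i0 <- floor((on - trace$t0_s) * fs) + 2L # first sample strictly after onset
    i1 <- min(n, floor((span_end - trace$t0_s) * fs) + 1L)
    if (i0 > i1) { dropped <- dropped + 1L; next }
    pk <- i0 + which.max(x[i0:i1]) - 1L
    if (pk - hspan >= 1L && pk + hspan - 1L <= n) {
      peaks <- c(peaks, pk)
    } else {
      dropped <- dropped + 1L
    }
  }
  if (!length(peaks)) return(dilation_events(dropped = dropped))
  met <- vapply(peaks, function(pk) {
    compute_event_metrics(trace, trace$t0_s + (pk - 1) / fs, cfg)
  }, numeric(2))
  dilation_events(
    peak_time_s = trace$t0_s + (peaks - 1) / fs,
    peak_index = peaks,
    label = rep("evoked", length(peaks)),
    baseline_z = met[1, ],
    amplitude_z = met[2, ],
    onset_start_s = NA_real_,
    onset_end_s = NA_real_,
    dropped = dropped
  )
}

#' Baseline and amplitude of one dilation event
#'
#' Baseline is the mean of the trace over `baseline_window_s` (default
#' [-6, -4) s) relative to the peak; amplitude is the mean over
#' `amplitude_window_s` (default [-2.5, 2.5) s) minus the baseline. Windows
#' are half-open, left-inclusive, evaluated on the sample grid.
#'
#' @param trace a preprocessed [pupil_trace()].
#' @param peak_time_s peak time in seconds.
#' @param cfg a [detection_config()].
#' @return named numeric vector `c(baseline_z, amplitude_z)`.
#' @export
compute_event_metrics <- function(trace, peak_time_s, cfg = detection_config()) {
  stopifnot(inherits(trace, "pupil_trace"))
  fs <- trace$rate_hz
  n <- length(trace$values)
  win_mean <- function(w) {
    i0 <- round((peak_time_s + w[1] - trace$t0_s) * fs) + 1L
    i1 <- round((peak_time_s + w[2] - trace$t0_s) * fs) # half-open: excludes w[2]
    assert_that(i0 >= 1L && i1 <= n, "boundary error: metric window leaves the trace")
    mean(trace$values[i0:i1])
  }
  baseline <- win_mean(cfg$baseline_window_s)
  amplitude <- win_mean(cfg$amplitude_window_s) - baseline
  c(baseline_z = baseline, amplitude_z = amplitude)
}

#' Extract peak-aligned trial rows from a 100 Hz series
#'
#' Each row is the series on `[peak - halfspan_s, peak + halfspan_s)`,
#' sampled on the 0.01 s grid (`2 * halfspan_s * 100` columns). Rows are
#' ordered by peak time; events whose window would leave the series are
#' dropped and counted.
#'
#' @param series any object with `values`, `rate_hz` (100) and `t0_s`
#'   fields: a [pupil_trace()], a band-power series, or a plain list.
#' @param events a `dilation_events` data.frame (or anything with a
#'   `peak_time_s` column).
#' @param halfspan_s half-width of the aligned window in seconds.
#' @return list with `matrix` (n_events x n_samples), `times_rel_s` (the
#'   shared relative timebase), `events` (the retained rows) and `dropped`.
#' @export
align_to_peaks <- function(series, events, halfspan_s = 6) {
  assert_that(!is.null(series$values) && !is.null(series$rate_hz),
              "series must carry values and rate_hz")
  fs <- series$rate_hz
  x <- series$values
  n <- length(x)
  ncol_out <- round(2 * halfspan_s * fs)
  times_rel <- (seq_len(ncol_out) - 1) / fs - halfspan_s
  if (NROW(events) == 0) {
    return(list(matrix = matrix(numeric(0), nrow = 0, ncol = ncol_out),
                times_rel_s = times_rel, events = events, dropped = 0L))
  }
  starts <- round((events$peak_time_s - halfspan_s - series$t0_s) * fs) + 1L
  keep <- starts >= 1L & (starts + ncol_out - 1L) <= n
  dropped <- sum(!keep)
  starts <- starts[keep]
  ord <- order(events$peak_time_s[keep])
  starts <- starts[ord]
  kept_events <- events[keep, , drop = FALSE][ord, , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(starts), ncol = ncol_out)
  for (r in seq_along(starts)) {
    m[r, ] <- x[starts[r]:(starts[r] + ncol_out - 1L)]
  }
  list(matrix = m, times_rel_s = times_rel, events = kept_events,
       dropped = dropped)
}
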