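## Zero-phase IIR filtering with reflection padding.
##
## All filtering in the pipeline is noncausal ("zero-phase"): the filter is
## applied forward and backward so the output carries no phase lag and the
## effective magnitude response is the square of the one-pass response.
## Plain forward-backward filtering is badly behaved at the trace edges, so
## the input is extended at both ends by point-symmetric reflection (the
## standard padtype="odd" convention) before filtering and trimmed after.

#' Apply a filter forward and backward with symmetric edge padding
#'
#' @param filt a filter object as returned by [signal::butter()], or a list
#'   with `b`/`a` coefficient vectors.
#' @param x numeric signal.
#' @param pad number of samples of point-symmetric reflection appended at
#'   each end before filtering (capped at `length(x) - 1`).
#' @return the zero-phase filtered signal, same length as `x`.
#' @keywords internal
zero_phase <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(as.integer(pad), n - 1L)
  if (pad > 0L) {
    left <- 2 * x[1L] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  sections <- if (!is.null(filt$sos)) filt$sos else list(filt)
  y <- xp
  for (sec in sections) {
    y <- signal::filtfilt(signal::Arma(b = sec$b, a = sec$a), y)
  }
  if (pad > 0L) y[(pad + 1L):(pad + n)] else y
}

## Butterworth designs used by the pipeline ------------------------------

## 4th-order low-pass, pupil trace (cutoff 3.5 Hz at 10 Hz sampling)
pupil_lowpass <- function(rate_hz, cutoff_hz = 3.5) {
  signal::butter(4, cutoff_hz / (rate_hz / 2), type = "low")
}

## 4th-order high-pass removing slow drift (cutoff 0.1 Hz at 100 Hz).
## The cutoff sits ~3 decades below Nyquist, where a direct 4th-order
## transfer function loses ~8 digits to coefficient cancellation, so the
## filter is built as cascaded Butterworth second-order sections (bilinear
## transform of the factored analog prototype).
pupil_highpass <- function(rate_hz, cutoff_hz = 0.1, order = 4) {
  stopifnot(order %% 2 == 0)
  wc <- tan(pi * cutoff_hz / rate_hz) # prewarped analog cutoff
  sos <- lapply(seq_len(order / 2), function(k) {
    ck <- 2 * sin((2 * k - 1) * pi / (2 * order)) # Butterworth pair damping
    a0 <- 1 + ck * wc + wc^2
    list(b = c(1, -2, 1) / a0,
         a = c(1, 2 * (wc^2 - 1) / a0, (1 - ck * wc + wc^2) / a0))
  })
  list(sos = sos)
}

## 6th-order low-pass for EEG (cutoff 100 Hz at 1000 Hz sampling)
eeg_lowpass <- function(rate_hz, cutoff_hz = 100) {
  signal::butter(6, cutoff_hz / (rate_hz / 2), type = "low")
}

#' Second-order IIR notch (biquad), constrained-pole design
#'
#' Standard audio-EQ notch with centre frequency `f0` and quality factor
#' `q`; the zeros sit exactly on the unit circle at `f0` so the centre
#' frequency is fully rejected.
#'
#' @param f0 centre frequency in Hz.
#' @param rate_hz sampling rate in Hz.
#' @param q quality factor (centre frequency / -3 dB bandwidth).
#' @keywords internal
notch_filter <- function(f0, rate_hz, q = 30) {
  w0 <- 2 * pi * f0 / rate_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

## Analytic squared (zero-phase) Butterworth magnitude, used by tests as an
## independent oracle for attenuation levels.
butter_mag2 <- function(f, cutoff_hz, order, type = c("low", "high")) {
  type <- match.arg(type)
  u <- f / cutoff_hz
  h2 <- if (type == "low") 1 / (1 + u^(2 * order)) else u^(2 * order) / (1 + u^(2 * order))
  h2 # one-pass power response; zero-phase amplitude response equals h2
}
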