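## Spectral parameterization: aperiodic 1/f-with-knee backbone plus up to
## three Gaussian peaks, fitted on the log10 spectrum.
##
## Model: log10 PSD(f) ~ [b - log10(k + f^chi)] + sum_j h_j *
## exp(-(f - c_j)^2 / (2 s_j^2)). The procedure mirrors the standard
## spectral-parameterization loop: robust aperiodic fit, peak extraction on
## the flattened spectrum, joint Gaussian refit, final aperiodic refit on the
## peak-removed spectrum.

aperiodic_values <- function(f, b, k, chi) b - log10(k + f^chi)

gaussian_values <- function(f, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) return(numeric(length(f)))
  out <- numeric(length(f))
  for (j in seq_len(nrow(peaks))) {
    sdv <- peaks$width_hz[j] / 2
    out <- out + peaks$height[j] * exp(-(f - peaks$center_hz[j])^2 / (2 * sdv^2))
  }
  out
}

## Bounded least-squares fit of the aperiodic component on log10 power.
fit_ap_params <- function(f, L, init = NULL) {
  init <- init %||% c(b = L[1] + log10(1 + f[1]), k = 1, chi = 1)
  fit <- try(minpack.lm::nls.lm(
    par = init,
    lower = c(-Inf, 0, 0), upper = c(Inf, Inf, 10),
    fn = function(p) L - aperiodic_values(f, p[1], p[2], p[3]),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                         ptol = 1e-10)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(par = init, converged = FALSE))
  }
  list(par = stats::coef(fit), converged = fit$info %in% 1:4)
}

## Robust variant: fit, then refit on the points least affected by peaks
## (lowest 80% of positive residuals), as in standard implementations.
fit_ap_robust <- function(f, L) {
  first <- fit_ap_params(f, L)
  res <- L - aperiodic_values(f, first$par[1], first$par[2], first$par[3])
  keep <- res <= quantile(res, 0.8)
  if (sum(keep) >= 5) {
    second <- fit_ap_params(f[keep], L[keep], init = first$par)
    if (second$converged || !first$converged) return(second)
  }
  first
}

## Fit up to max_n Gaussians iteratively on a flattened log-spectrum, then
## refit all jointly.
fit_gaussians <- function(f, flat, max_n, min_height, width_limits) {
  sd_lims <- width_limits / 2
  peaks <- data.frame(center_hz = numeric(0), height = numeric(0),
                      width_hz = numeric(0))
  work <- flat
  for (j in seq_len(max_n)) {
    i_max <- which.max(work)
    h0 <- work[i_max]
    if (!is.finite(h0) || h0 < min_height) break
    c0 <- f[i_max]
    # half-height extent as the width guess
    half <- h0 / 2
    li <- i_max; while (li > 1 && work[li] > half) li <- li - 1
    ri <- i_max; while (ri < length(f) && work[ri] > half) ri <- ri + 1
    fwhm <- max(f[ri] - f[li], diff(range(f)) / length(f))
    s0 <- min(max(fwhm / 2.355, sd_lims[1]), sd_lims[2])
    par0 <- c(c = c0, h = h0, s = s0)
    fit <- try(minpack.lm::nls.lm(
      par = par0,
      lower = c(min(f), min_height / 2, sd_lims[1]),
      upper = c(max(f), Inf, sd_lims[2]),
      fn = function(p) work - p[2] * exp(-(f - p[1])^2 / (2 * p[3]^2)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    p <- if (inherits(fit, "try-error")) par0 else stats::coef(fit)
    g <- p[2] * exp(-(f - p[1])^2 / (2 * p[3]^2))
    work <- work - g
    peaks <- rbind(peaks, data.frame(center_hz = p[1], height = p[2],
                                     width_hz = 2 * p[3]))
  }
  if (nrow(peaks) == 0) return(peaks)
  # joint refit of all Gaussians on the original flattened spectrum
  par0 <- as.numeric(t(as.matrix(
    data.frame(peaks$center_hz, peaks$height, peaks$width_hz / 2))))
  np <- nrow(peaks)
  lower <- rep(c(min(f), min_height / 2, sd_lims[1]), np)
  upper <- rep(c(max(f), Inf, sd_lims[2]), np)
  fitj <- try(minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) {
      model <- numeric(length(f))
      for (q in seq_len(np)) {
        cc <- p[3 * q - 2]; hh <- p[3 * q - 1]; ss <- p[3 * q]
        model <- model + hh * exp(-(f - cc)^2 / (2 * ss^2))
      }
      flat - model
    },
    control = minpack.lm::nls.lm.control(maxiter = 500)
  ), silent = TRUE)
  if (!inherits(fitj, "try-error")) {
    p <- stats::coef(fitj)
    peaks <- data.frame(center_hz = p[seq(1, 3 * np, 3)],
                        height = p[seq(2, 3 * np, 3)],
                        width_hz = 2 * p[seq(3, 3 * np, 3)])
  }
  peaks[peaks$height >= min_height, , drop = FALSE]
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Fits `log10 PSD(f) = b - log10(k + f^chi)` plus up to `max_n_peaks`
#' Gaussian peaks over `fit_range`. The procedure is: robust aperiodic fit;
#' peak extraction on the flattened spectrum (tallest first, stopping below
#' `min_peak_height`); joint Gaussian refit; final aperiodic refit on the
#' peak-removed spectrum. Goodness is the R-squared of the full model on the
#' log10 spectrum.
#'
#' @param spec a [spectrum_estimate()] covering `fit_range` with strictly
#'   positive psd there.
#' @param fit_range frequency range of the fit in Hz (default 2-55 Hz,
#'   bounded away from the 60 Hz notch).
#' @param max_n_peaks maximum number of Gaussian peaks.
#' @param min_peak_height minimum peak height in log10-power units.
#' @param peak_width_limits allowed peak widths (Hz), stored as twice the
#'   Gaussian standard deviation.
#' @return an object of class `aperiodic_fit`: list with `offset`, `knee`,
#'   `exponent`, `peaks` (data.frame `center_hz`, `height`, `width_hz`),
#'   `r_squared`, `fit_range`, `converged`.
#' @export
fit_aperiodic <- function(spec, fit_range = c(2, 55), max_n_peaks = 3,
                          min_peak_height = 0.1, peak_width_limits = c(2, 10)) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  sel <- spec$freqs >= fit_range[1] & spec$freqs <= fit_range[2]
  f <- spec$freqs[sel]
  p <- spec$psd[sel]
  assert_that(length(f) >= 8, "spectrum must cover the fit range")
  assert_that(all(p > 0), "psd must be positive on the fit range")
  L <- log10(p)

  ap1 <- fit_ap_robust(f, L)
  flat <- L - aperiodic_values(f, ap1$par[1], ap1$par[2], ap1$par[3])
  peaks <- fit_gaussians(f, flat, max_n_peaks, min_peak_height,
                         peak_width_limits)
  peak_model <- gaussian_values(f, peaks)
  ap2 <- fit_ap_params(f, L - peak_model, init = ap1$par)
  # chi ~ 0 leaves offset and knee jointly unidentified (the aperiodic term
  # is the constant b - log10(k + 1)); report the canonical k = 0 form.
  if (ap2$par[3] < 1e-3) {
    ap2$par[1] <- ap2$par[1] - log10(ap2$par[2] + 1)
    ap2$par[2] <- 0
  }
  model <- aperiodic_values(f, ap2$par[1], ap2$par[2], ap2$par[3]) + peak_model
  r2 <- 1 - sum((L - model)^2) / max(sum((L - mean(L))^2), .Machine$double.eps)

  structure(list(offset = unname(ap2$par[1]), knee = unname(ap2$par[2]),
                 exponent = unname(ap2$par[3]), peaks = peaks,
                 r_squared = r2, fit_range = fit_range,
                 converged = ap2$converged && ap1$converged),
            class = "aperiodic_fit")
}

#' @exportS3Method base::print
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> offset %.3f, knee %.3f, exponent %.3f (R^2 %.4f%s)\n",
              x$offset, x$knee, x$exponent, x$r_squared,
              if (x$converged) "" else ", NOT converged"))
  if (nrow(x$peaks)) {
    for (j in seq_len(nrow(x$peaks))) {
      cat(sprintf("  peak %d: %.2f Hz, height %.3f, width %.2f Hz\n", j,
                  x$peaks$center_hz[j], x$peaks$height[j], x$peaks$width_hz[j]))
    }
  }
  invisible(x)
}
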