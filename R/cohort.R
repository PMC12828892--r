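## Controlled trial cohorts for classifier calibration and power studies.

#' Simulate a labeled cohort of peak-aligned band-power trials
#'
#' Generates one long synthetic EEG session carrying `n_trials` dilation
#' events at fixed spacing with a balanced, shuffled class assignment, runs
#' the standard EEG pipeline (filtering, sliding band power) and extracts
#' the peak-aligned windows per band at the ground-truth peaks. This is the
#' generator used to ask calibration questions ("are the classifiers at
#' chance when the two classes are statistically identical?") and power
#' questions ("which band separates the classes when only one band's
#' coupling differs?"), because the class contrast is known exactly.
#'
#' @param n_trials number of trials (must be even; half per class).
#' @param config a [sim_config()]; its `band_coupling` defines the
#'   class-specific envelope gains. Duration is ignored and recomputed from
#'   the trial count and spacing.
#' @param spacing_s separation between consecutive event peaks (s); must
#'   exceed the 12 s aligned window plus kernel decay.
#' @param halfspan_s half-width of the aligned trial window (s).
#' @param seed seed controlling the class shuffle and the EEG noise.
#' @return named list of `trial_matrix` objects, one per canonical band,
#'   sharing the identical trial set; the planted `events` data.frame is
#'   attached as an attribute.
#' @export
simulate_trial_cohort <- function(n_trials, config = NULL, spacing_s = 16,
                                  halfspan_s = 6, seed = 1L) {
  assert_that(n_trials %% 2 == 0, "n_trials must be even (balanced classes)")
  assert_that(spacing_s >= 2 * halfspan_s + 2,
              "spacing must exceed the aligned window")
  margin <- halfspan_s + 4
  duration <- 2 * margin + (n_trials - 1) * spacing_s
  if (is.null(config)) config <- sim_config(duration_s = duration, seed = seed)
  config$duration_s <- duration
  config$seed <- as.integer(seed)

  peaks <- margin + (seq_len(n_trials) - 1) * spacing_s
  labels <- withr::with_seed(child_seed(seed, 6L), {
    sample(rep(c("spontaneous", "evoked"), n_trials / 2))
  })
  eeg <- simulate_eeg(config, peaks, labels)
  eeg <- preprocess_eeg(eeg)
  bp <- sliding_band_power(eeg)

  events <- dilation_events(
    peak_time_s = peaks, peak_index = round(peaks * 100) + 1L,
    label = labels, baseline_z = NA_real_, amplitude_z = NA_real_,
    onset_start_s = NA_real_, onset_end_s = NA_real_)

  out <- lapply(bp, function(series) {
    al <- align_to_peaks(series, events, halfspan_s)
    tm <- trial_matrix(al$matrix,
                       ifelse(al$events$label == "evoked", 1L, 0L),
                       band = series$band$name)
    tm$times_rel_s <- al$times_rel_s
    tm
  })
  attr(out, "events") <- events
  attr(out, "config") <- config
  out
}

#' Convert a trial matrix to aligned band trials
#'
#' @param tm a `trial_matrix` with a recorded timebase.
#' @return an [aligned_band_trials()] with the same rows and labels.
#' @export
as_aligned_band_trials <- function(tm) {
  stopifnot(inherits(tm, "trial_matrix"))
  aligned_band_trials(tm$band, tm$features,
                      labels = ifelse(tm$labels == 1L, "evoked", "spontaneous"),
                      times_rel_s = tm$times_rel_s,
                      session_ids = tm$session_ids)
}
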