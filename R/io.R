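## Plain-text readers and writers for the session formats.

#' Read a pupil CSV (time_s, pupil)
#' @param path CSV file with columns `time_s`, `pupil`.
#' @return a [pupil_trace()] (rate inferred from the time column).
#' @export
read_pupil_csv <- function(path) {
  d <- read.csv(path)
  assert_that(all(c("time_s", "pupil") %in% names(d)),
              "pupil CSV needs time_s and pupil columns")
  dt <- diff(d$time_s)
  assert_that(max(abs(dt - dt[1])) < 1e-6, "pupil samples must be uniform")
  pupil_trace(d$pupil, rate_hz = 1 / dt[1], t0_s = d$time_s[1])
}

#' Read an EEG CSV (time_s, eeg_uV)
#' @param path CSV file with columns `time_s`, `eeg_uV`.
#' @return an [eeg_trace()].
#' @export
read_eeg_csv <- function(path) {
  d <- read.csv(path)
  assert_that(all(c("time_s", "eeg_uV") %in% names(d)),
              "EEG CSV needs time_s and eeg_uV columns")
  dt <- diff(d$time_s[1:min(1000, nrow(d))])
  eeg_trace(d$eeg_uV, rate_hz = round(1 / dt[1]), t0_s = d$time_s[1])
}

#' Read a stimulation-onset CSV (onset_s, duration_s)
#' @param path CSV path.
#' @return data.frame with `onset_s`, `duration_s`.
#' @export
read_stim_csv <- function(path) {
  d <- read.csv(path)
  assert_that("onset_s" %in% names(d), "stim CSV needs an onset_s column")
  if (is.null(d$duration_s)) d$duration_s <- NA_real_
  d
}

#' Read a blink-interval CSV (start_s, end_s)
#' @param path CSV path.
#' @return two-column data.frame.
#' @export
read_blink_csv <- function(path) {
  d <- read.csv(path)
  assert_that(all(c("start_s", "end_s") %in% names(d)),
              "blink CSV needs start_s and end_s columns")
  d[, c("start_s", "end_s")]
}

fmt_num <- function(x) formatC(x, digits = 10, format = "g")

#' Write a synthetic session to CSV files
#'
#' Writes `pupil.csv` (time_s, pupil), `eeg.csv` (time_s, eeg_uV),
#' `events.csv` (peak_s, label), `stim.csv` (onset_s, duration_s) and
#' `config.yaml` into `dir`.
#'
#' @param session a `sim_session`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "sim_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- character(0)
  p <- file.path(dir, "pupil.csv")
  write.csv(data.frame(time_s = fmt_num(trace_times(session$pupil)),
                       pupil = fmt_num(session$pupil$values)),
            p, row.names = FALSE, quote = FALSE)
  f <- c(f, p)
  p <- file.path(dir, "eeg.csv")
  write.csv(data.frame(time_s = fmt_num(trace_times(session$eeg)),
                       eeg_uV = fmt_num(session$eeg$values)),
            p, row.names = FALSE, quote = FALSE)
  f <- c(f, p)
  p <- file.path(dir, "events.csv")
  write.csv(data.frame(peak_s = fmt_num(session$truth_events$peak_time_s),
                       label = session$truth_events$label),
            p, row.names = FALSE, quote = FALSE)
  f <- c(f, p)
  p <- file.path(dir, "stim.csv")
  write.csv(data.frame(onset_s = fmt_num(session$stim_onsets),
                       duration_s = fmt_num(rep(session$config$stim_duration_s,
                                                length(session$stim_onsets)))),
            p, row.names = FALSE, quote = FALSE)
  f <- c(f, p)
  p <- file.path(dir, "config.yaml")
  cfg <- unclass(session$config)
  if (!is.null(cfg$band_coupling)) {
    cfg$band_coupling <- lapply(seq_len(nrow(cfg$band_coupling)), function(i) {
      as.list(cfg$band_coupling[i, , drop = FALSE])
    })
  }
  yaml::write_yaml(cfg, p)
  f <- c(f, p)
  invisible(f)
}

#' Write a dilation-events table to CSV
#' @param events a `dilation_events` data.frame.
#' @param path output CSV.
#' @export
write_events_csv <- function(events, path) {
  write.csv(data.frame(peak_s = fmt_num(events$peak_time_s),
                       label = events$label,
                       baseline_z = fmt_num(events$baseline_z),
                       amplitude_z = fmt_num(events$amplitude_z)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
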