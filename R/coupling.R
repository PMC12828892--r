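## Peak-aligned coupling statistics: pre/during/post window power, pointwise
## group tests across the aligned timebase, event-metric comparisons and
## interdilation intervals.

#' Construct an aligned-band-trials container
#'
#' @param band band name.
#' @param matrix n_trials x n_timepoints matrix of band power, rows aligned
#'   to dilation peaks.
#' @param labels class per trial (`"spontaneous"`/`"evoked"`), optional.
#' @param times_rel_s shared relative timebase (s), one per column.
#' @param session_ids per-trial session identifier, optional.
#' @return an object of class `aligned_band_trials`.
#' @export
aligned_band_trials <- function(band, matrix, labels = NULL,
                                times_rel_s = NULL, session_ids = NULL) {
  assert_that(is.matrix(matrix) && all(is.finite(matrix)),
              "trial matrix must be finite")
  times_rel_s <- times_rel_s %||%
    ((seq_len(ncol(matrix)) - 1) / 100 - ncol(matrix) / 200)
  assert_that(length(times_rel_s) == ncol(matrix),
              "timebase must match the number of columns")
  if (!is.null(labels)) {
    assert_that(length(labels) == nrow(matrix), "one label per trial required")
  }
  structure(list(band = band, matrix = matrix, labels = labels,
                 times_rel_s = times_rel_s,
                 session_ids = session_ids %||% rep(1L, nrow(matrix))),
            class = "aligned_band_trials")
}

#' @exportS3Method base::print
print.aligned_band_trials <- function(x, ...) {
  cat(sprintf("<aligned_band_trials> %s: %d trials x %d timepoints [%g, %g) s\n",
              x$band, nrow(x$matrix), ncol(x$matrix),
              min(x$times_rel_s), max(x$times_rel_s) + diff(x$times_rel_s[1:2])))
  invisible(x)
}

#' Mean band power in pre/during/post windows around the peak
#'
#' Computes each trial's mean power within the three 5 s periods
#' [-7.5, -2.5), [-2.5, 2.5) and [2.5, 7.5) seconds relative to the dilation
#' peak (half-open, left-inclusive), then aggregates with mean and standard
#' error across trials or sessions.
#'
#' @param trials an [aligned_band_trials()] whose timebase covers the spans
#'   (alignment at halfspan 7.5 s).
#' @param spans named list of `c(start, end)` spans in seconds.
#' @param by aggregation unit, `"trial"` or `"session"`.
#' @return an object of class `window_stats`: list with `band`, `per_trial`
#'   (data.frame, one row per trial x period), `summary` (period, mean, sem,
#'   n).
#' @export
window_band_power <- function(trials,
                              spans = list(pre = c(-7.5, -2.5),
                                           during = c(-2.5, 2.5),
                                           post = c(2.5, 7.5)),
                              by = c("trial", "session")) {
  stopifnot(inherits(trials, "aligned_band_trials"))
  by <- match.arg(by)
  tb <- trials$times_rel_s
  dt <- tb[2] - tb[1]
  per <- lapply(names(spans), function(nm) {
    sp <- spans[[nm]]
    sel <- tb >= sp[1] - dt / 2 & tb < sp[2] - dt / 2
    assert_that(any(sel), sprintf("span [%g, %g) outside the trial window",
                                  sp[1], sp[2]))
    assert_that(sp[1] >= tb[1] - dt / 2 - 1e-9 &&
                  sp[2] <= tb[length(tb)] + dt + 1e-9,
                sprintf("span [%g, %g) outside the trial window", sp[1], sp[2]))
    rowMeans(trials$matrix[, sel, drop = FALSE])
  })
  names(per) <- names(spans)
  per_trial <- data.frame(
    trial = rep(seq_len(nrow(trials$matrix)), times = length(spans)),
    session = rep(trials$session_ids, times = length(spans)),
    period = rep(names(spans), each = nrow(trials$matrix)),
    power = unlist(per, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  unit <- if (by == "trial") per_trial$trial else per_trial$session
  agg <- lapply(names(spans), function(nm) {
    v <- per_trial$power[per_trial$period == nm]
    u <- unit[per_trial$period == nm]
    vu <- tapply(v, u, mean)
    data.frame(period = nm, mean = mean(vu), sem = sd(vu) / sqrt(length(vu)),
               n = length(vu), stringsAsFactors = FALSE)
  })
  structure(list(band = trials$band, per_trial = per_trial,
                 summary = do.call(rbind, agg), by = by, spans = spans),
            class = "window_stats")
}

#' Pointwise two-sample t-test along the aligned timebase
#'
#' Two-sided unpaired Student t-test (pooled variance) at every time point,
#' reported the way peri-event comparisons are usually summarized: the
#' count of significant points and the percentage of the time series they
#' cover. P-values are uncorrected by default; Benjamini-Hochberg FDR is
#' available via `correct = "BH"`.
#'
#' @param group_a,group_b [aligned_band_trials()] on identical timebases,
#'   each with at least 2 trials.
#' @param alpha significance level.
#' @param correct `"none"` (default) or `"BH"`.
#' @return an object of class `pointwise_test`: list with `t_values`,
#'   `p_values`, `significant_mask`, `n_significant`, `pct_significant`,
#'   `times_rel_s`, `alpha`.
#' @export
pointwise_group_test <- function(group_a, group_b, alpha = 0.05,
                                 correct = c("none", "BH")) {
  stopifnot(inherits(group_a, "aligned_band_trials"),
            inherits(group_b, "aligned_band_trials"))
  correct <- match.arg(correct)
  assert_that(isTRUE(all.equal(group_a$times_rel_s, group_b$times_rel_s)),
              "groups must share the aligned timebase")
  a <- group_a$matrix
  b <- group_b$matrix
  n1 <- nrow(a); n2 <- nrow(b)
  assert_that(n1 >= 2 && n2 >= 2, "at least 2 trials per group required")
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tv <- (m1 - m2) / se
  df <- n1 + n2 - 2
  pv <- 2 * pt(-abs(tv), df)
  zero_var <- se == 0 | !is.finite(se)
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance time points set to p = 1", sum(zero_var)))
    tv[zero_var] <- 0
    pv[zero_var] <- 1
  }
  p_adj <- if (correct == "BH") stats::p.adjust(pv, "BH") else pv
  mask <- p_adj < alpha
  structure(list(t_values = tv, p_values = pv, significant_mask = mask,
                 n_significant = sum(mask),
                 pct_significant = 100 * sum(mask) / length(mask),
                 times_rel_s = group_a$times_rel_s, alpha = alpha,
                 correct = correct, df = df),
            class = "pointwise_test")
}

#' @exportS3Method base::print
print.pointwise_test <- function(x, ...) {
  cat(sprintf("<pointwise_test> %d significant time points, %.1f%% of time series (alpha %g%s)\n",
              x$n_significant, x$pct_significant, x$alpha,
              if (x$correct != "none") paste0(", ", x$correct) else ""))
  invisible(x)
}

#' Compare baseline and amplitude between two event sets
#'
#' Two-sided unpaired Student t-tests on `baseline_z` and `amplitude_z`.
#' Normality of each metric is screened with a Shapiro-Wilk test on the
#' pooled, group-centred values; when it fails (p < 0.05) the rank-sum
#' (Mann-Whitney U) p-value is reported as primary instead, and the report
#' says so. Both p-values are always included.
#'
#' @param events_a,events_b `dilation_events` data.frames (>= 2 events each).
#' @return data.frame with one row per metric: group means, difference,
#'   `p_t`, `p_ranksum`, `primary` and `primary_p`.
#' @export
compare_event_metrics <- function(events_a, events_b) {
  assert_that(NROW(events_a) >= 2 && NROW(events_b) >= 2,
              "at least 2 events per side required")
  one <- function(metric) {
    va <- events_a[[metric]]
    vb <- events_b[[metric]]
    pooled <- c(va - mean(va), vb - mean(vb))
    normal <- tryCatch({
      if (length(unique(pooled)) < 3) FALSE
      else shapiro.test(pooled[seq_len(min(length(pooled), 5000))])$p.value >= 0.05
    }, error = function(e) FALSE)
    p_t <- tryCatch(t.test(va, vb, var.equal = TRUE)$p.value,
                    error = function(e) 1)
    p_w <- tryCatch(suppressWarnings(wilcox.test(va, vb)$p.value),
                    error = function(e) 1)
    data.frame(metric = metric, mean_a = mean(va), mean_b = mean(vb),
               difference = mean(va) - mean(vb), p_t = p_t, p_ranksum = p_w,
               primary = if (normal) "t" else "ranksum",
               primary_p = if (normal) p_t else p_w,
               stringsAsFactors = FALSE)
  }
  rbind(one("baseline_z"), one("amplitude_z"))
}

#' Interdilation intervals
#'
#' Successive differences of event peak times with mean and median, the
#' summary used to characterize the frequency of phasic arousal events.
#'
#' @param events a `dilation_events` data.frame (any event table with a
#'   `peak_time_s` column).
#' @return list with `intervals_s`, `mean_s`, `median_s`, `n`.
#' @export
interdilation_intervals <- function(events) {
  pk <- sort(events$peak_time_s)
  iv <- if (length(pk) >= 2) diff(pk) else numeric(0)
  list(intervals_s = iv,
       mean_s = if (length(iv)) mean(iv) else NA_real_,
       median_s = if (length(iv)) median(iv) else NA_real_,
       n = length(iv))
}
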