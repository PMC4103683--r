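#' Detect transient onset
#'
#' Onset is the first time at or after `after_s` at which dF/F0 exceeds the
#' baseline mean plus `k` baseline standard deviations and stays above that
#' threshold, without a net decrease, for at least `m` consecutive samples.
#' Baseline statistics come from `baseline_window` (default: all samples
#' before `after_s`).
#'
#' @param dff a `dff_trace`.
#' @param after_s search from this time (s) onward.
#' @param k threshold in baseline SDs (default 2).
#' @param m sustained-rise run length in samples (default 3).
#' @param baseline_window optional length-2 numeric window for the baseline.
#' @return onset time (s), or `NA` when no transient is detected.
#' @export
detect_onset <- function(dff, after_s, k = 2, m = 3, baseline_window = NULL) {
  stopifnot(inherits(dff, "dff_trace"))
  res <- .onset_detect(dff$time_s, dff$dff_percent, after_s, k, m,
                       baseline_window)
  res$onset
}

.onset_detect <- function(tt, y, after_s, k, m, baseline_window = NULL) {
  if (after_s < tt[1] || after_s > tt[length(tt)])
    stop("after_s lies outside the trace", call. = FALSE)
  base_sel <- if (is.null(baseline_window)) tt < after_s else
    tt >= baseline_window[1] & tt <= baseline_window[2]
  if (!sum(base_sel))
    stop("no baseline samples available before after_s", call. = FALSE)
  thr <- mean(y[base_sel]) + k * sd_or_zero(y[base_sel])
  idx <- which(tt >= after_s)
  n <- length(y)
  for (i in idx) {
    j <- min(i + m - 1L, n)
    if (j - i + 1L < m) break
    run <- y[i:j]
    if (all(run > thr) && run[m] >= run[1])
      return(list(onset = tt[i], onset_idx = i, threshold = thr,
                  base_mean = mean(y[base_sel])))
  }
  list(onset = NA_real_, onset_idx = NA_integer_, threshold = thr,
       base_mean = mean(y[base_sel]))
}

# End of the suprathreshold epoch that starts at onset: the first time after
# onset at which the trace stays below the onset threshold for m consecutive
# samples (end = NA when it never returns to baseline). With hysteresis: the
# end-test is only armed once the trace has risen to twice the threshold
# excursion above baseline, so noise dips while the signal still sits near
# the threshold cannot cut the epoch short during a slow rise. A trace that
# never arms (never clears twice the detection band) carries no quantifiable
# transient; callers treat that as a no-transient bout.
.epoch_end <- function(tt, y, onset_idx, thr, m, base_mean = 0) {
  n <- length(y)
  if (onset_idx + m > n) return(list(end_s = NA_real_, armed = FALSE))
  thr_high <- base_mean + 2 * (thr - base_mean)
  below <- y < thr
  armed <- FALSE
  for (i in (onset_idx + 1L):n) {
    if (!armed) {
      if (y[i] >= thr_high) armed <- TRUE
      next
    }
    j <- i + m - 1L
    if (j > n) break
    if (all(below[i:j])) return(list(end_s = tt[i], armed = TRUE))
  }
  list(end_s = NA_real_, armed = armed)
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

#' Insertion-to-peak latency
#'
#' Time from spicule insertion to the calcium peak: the argmax of dF/F0 over
#' `[insertion, insertion + search_window_s]`, ties broken to the earliest
#' sample (latency is a minimum-time quantity).
#'
#' @param dff a `dff_trace`.
#' @param insertion_s insertion time (s); default: first `insertion` event in
#'   the trace's event log.
#' @param search_window_s length of the post-insertion search window
#'   (default 30 s; truncated at the end of the trace with a warning).
#' @return latency in seconds, with attribute `peak_time_s`.
#' @export
peak_latency <- function(dff, insertion_s = NULL, search_window_s = 30) {
  stopifnot(inherits(dff, "dff_trace"))
  if (is.null(insertion_s)) {
    ev <- attr(dff, "events")
    insertion_s <- ev[["insertion"]][1]
    if (is.null(insertion_s)) stop("no insertion event", call. = FALSE)
  }
  t_end <- insertion_s + search_window_s
  if (t_end > dff$time_s[nrow(dff)] + 1e-9) {
    warning("search window truncated at end of trace", call. = FALSE)
    t_end <- dff$time_s[nrow(dff)]
  }
  sel <- which(dff$time_s >= insertion_s & dff$time_s <= t_end + 1e-9)
  if (!length(sel)) stop("insertion lies outside the trace", call. = FALSE)
  pk <- sel[which.max(dff$dff_percent[sel])]   # which.max: earliest tie
  structure(dff$time_s[pk] - insertion_s, peak_time_s = dff$time_s[pk])
}

#' Rise slope of the initial calcium increase
#'
#' Ordinary least-squares slope of dF/F0 against time between onset and peak,
#' in %dF/F0 per second. No smoothing is applied.
#'
#' @param dff a `dff_trace`.
#' @param onset_s,peak_time_s segment boundaries (s), `onset_s < peak_time_s`.
#' @return slope in %/s.
#' @export
rise_slope <- function(dff, onset_s, peak_time_s) {
  stopifnot(inherits(dff, "dff_trace"))
  if (!(onset_s < peak_time_s))
    stop("onset must precede peak", call. = FALSE)
  sel <- dff$time_s >= onset_s - 1e-9 & dff$time_s <= peak_time_s + 1e-9
  if (sum(sel) < 2)
    stop("fewer than 2 samples between onset and peak", call. = FALSE)
  ols_slope(dff$time_s[sel], dff$dff_percent[sel])
}

ols_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

# Rise-slope segment placement for noisy traces: OLS on raw samples between
# the detected onset and half a smoothing window before the smoothed-trace
# argmax (see extract_kinetics). Falls back to the raw onset-to-peak segment
# when too few samples remain.
.rise_slope_guarded <- function(dff, onset_s, peak_time_s, w, min_samples) {
  tt <- dff$time_s
  dt <- tt[2] - tt[1]
  hi <- peak_time_s
  if (w > 1 && w %% 2 == 1 && nrow(dff) > w) {
    ys <- as.numeric(stats::filter(dff$dff_percent, rep(1 / w, w), sides = 2))
    sel <- which(tt >= onset_s & tt <= peak_time_s + 1 & !is.na(ys))
    if (length(sel)) {
      pk_sm <- tt[sel[which.max(ys[sel])]]
      cand <- pk_sm - (w %/% 2) * dt
      n_seg <- sum(tt >= onset_s - 1e-9 & tt <= cand + 1e-9)
      if (n_seg >= min_samples) hi <- cand else hi <- pk_sm
    }
  }
  if (hi <= onset_s) hi <- peak_time_s
  if (sum(tt >= onset_s - 1e-9 & tt <= hi + 1e-9) < 2) hi <- peak_time_s
  rise_slope(dff, onset_s, hi)
}

#' Second-rise (biphasic) features
#'
#' For biphasic transients, finds where dF/F0 begins to increase for a second
#' time after the first peak, the peak following that second increase, and
#' the straight-line slope between them. The second onset is detected with
#' the [detect_onset()] rule, using the second following the post-peak trough
#' as the local baseline; the trough is sought within `trough_window_s` of
#' the first peak so that late-trace features (e.g. post-release
#' oscillations) are not mistaken for the inter-peak dip.
#'
#' @param dff a `dff_trace`.
#' @param first_peak_s time of the first peak (s).
#' @param k,m onset-rule parameters passed to [detect_onset()].
#' @param trough_window_s how far past the first peak to search for the
#'   inter-peak trough (default 10 s).
#' @return list with `onset_s`, `peak_time_s`, `slope`, and logical
#'   `no_second_rise`.
#' @export
second_rise_features <- function(dff, first_peak_s, k = 2, m = 3,
                                 trough_window_s = 10) {
  stopifnot(inherits(dff, "dff_trace"))
  tt <- dff$time_s
  after <- which(tt > first_peak_s & tt <= first_peak_s + trough_window_s)
  none <- list(onset_s = NA_real_, peak_time_s = NA_real_,
               slope = NA_real_, no_second_rise = TRUE)
  if (length(after) < 2 * m) return(none)
  trough_i <- after[which.min(dff$dff_percent[after])]
  trough_t <- tt[trough_i]
  if (trough_i >= nrow(dff) - m) return(none)     # monotone decay to the end
  onset <- detect_onset(dff, after_s = trough_t, k = k, m = m,
                        baseline_window = c(trough_t, trough_t + 1))
  if (is.na(onset)) return(none)
  sel <- which(tt >= onset)
  pk <- sel[which.max(dff$dff_percent[sel])]
  if (tt[pk] <= onset) return(none)
  list(onset_s = onset, peak_time_s = tt[pk],
       slope = .rise_slope_guarded(dff, onset, tt[pk], 7, 6),
       no_second_rise = FALSE)
}

#' Post-peak 15 s slope
#'
#' Straight-line (OLS) slope of dF/F0 over the 15 s following the highest
#' calcium transient, a window chosen to include sperm release. When fewer
#' than `window_s` seconds remain after the peak, the slope is computed on
#' the available samples and flagged with attribute `truncated = TRUE`.
#'
#' @param dff a `dff_trace`.
#' @param window_s window length after the global peak (default 15 s).
#' @return slope in %/s, with attribute `truncated`.
#' @export
post_peak_15s_slope <- function(dff, window_s = 15) {
  stopifnot(inherits(dff, "dff_trace"))
  pk <- which.max(dff$dff_percent)
  if (pk == nrow(dff))
    stop("global peak is the final sample; no post-peak window", call. = FALSE)
  t_pk <- dff$time_s[pk]
  t_end <- t_pk + window_s
  truncated <- FALSE
  if (t_end > dff$time_s[nrow(dff)] + 1e-9) {
    truncated <- TRUE
    warning("fewer than ", window_s, " s remain after the peak; ",
            "slope computed on available samples", call. = FALSE)
    t_end <- dff$time_s[nrow(dff)]
  }
  sel <- dff$time_s >= t_pk & dff$time_s <= t_end + 1e-9
  structure(ols_slope(dff$time_s[sel], dff$dff_percent[sel]),
            truncated = truncated)
}

#' Extract all event-aligned kinetic features from one bout
#'
#' Convenience wrapper running [detect_onset()], [peak_latency()],
#' [rise_slope()], [second_rise_features()] and [post_peak_15s_slope()] on a
#' dF/F0 trace.
#'
#' Bouts in which no transient is detected (the onset rule never fires) are
#' flagged `no_transient` and all transient features are `NA`; they drop out
#' of [summarize_cohort()], mirroring the practice of only quantifying
#' recordings with a visible transient. For detected transients the peak
#' search is restricted to the contiguous suprathreshold epoch that begins
#' at onset (the transient itself), so an isolated noise excursion elsewhere
#' in the search window cannot be mistaken for the peak.
#'
#' The rise slope is an OLS fit on the raw (unsmoothed) dF/F0 samples, but
#' the segment endpoints are placed with the help of a centered moving
#' average of odd width `slope_smooth_w` (smoothing is used for endpoint
#' placement only, never for the fitted values): the segment runs from the
#' detected onset to half a smoothing window before the smoothed-trace
#' argmax. Ending the fit at the raw argmax sample would bias the slope
#' upward, because that sample's noise is positively selected; ending it
#' just before the smoothed peak keeps every fitted sample on the rising
#' limb. Segments shorter than `slope_min_samples` fall back to the full
#' onset-to-peak segment.
#'
#' @param dff a `dff_trace` whose event log contains an `insertion` event
#'   (or pass `insertion_s`).
#' @param insertion_s insertion time (s).
#' @param search_window_s peak search window (s).
#' @param k,m onset-rule parameters.
#' @param biphasic also search for a second rise after the first peak.
#' @param slope_smooth_w odd moving-average width (samples) used to place
#'   the rise-slope segment endpoints; 1 disables smoothing.
#' @param slope_min_samples minimum samples in the slope segment before
#'   falling back to the full onset-to-peak segment.
#' @return an object of class `kinetic_features` (named list).
#' @export
extract_kinetics <- function(dff, insertion_s = NULL, search_window_s = 30,
                             k = 2, m = 3, biphasic = FALSE,
                             slope_smooth_w = 7, slope_min_samples = 6) {
  stopifnot(inherits(dff, "dff_trace"))
  if (is.null(insertion_s)) {
    ev <- attr(dff, "events")
    insertion_s <- ev[["insertion"]][1]
    if (is.null(insertion_s)) stop("no insertion event", call. = FALSE)
  }
  det <- .onset_detect(dff$time_s, dff$dff_percent, insertion_s, k, m)
  onset <- det$onset
  feats <- list(
    onset_s = NA_real_, peak_time_s = NA_real_,
    insertion_to_peak_s = NA_real_, rise_slope = NA_real_,
    post_peak_15s_slope = NA_real_,
    second_rise_onset_s = NA_real_, second_peak_time_s = NA_real_,
    second_insertion_to_peak_s = NA_real_, second_rise_slope = NA_real_,
    no_transient = TRUE
  )
  if (is.na(onset)) return(structure(feats, class = "kinetic_features"))
  # confine the peak search to the transient's own suprathreshold epoch; a
  # trace that never clears twice the detection band has no quantifiable
  # transient, only a threshold-grazing fluctuation
  ep <- .epoch_end(dff$time_s, dff$dff_percent, det$onset_idx,
                   det$threshold, m, det$base_mean)
  if (!ep$armed) return(structure(feats, class = "kinetic_features"))
  win <- if (is.na(ep$end_s)) search_window_s else
    min(search_window_s, ep$end_s - insertion_s)
  lat <- suppressWarnings(peak_latency(dff, insertion_s, win))
  peak_t <- attr(lat, "peak_time_s")
  slope <- if (onset < peak_t)
    .rise_slope_guarded(dff, onset, peak_t, slope_smooth_w,
                        slope_min_samples) else NA_real_
  feats$onset_s <- onset
  feats$peak_time_s <- peak_t
  feats$insertion_to_peak_s <- as.numeric(lat)
  feats$rise_slope <- slope
  feats$post_peak_15s_slope <- as.numeric(post_peak_15s_slope(dff))
  feats$no_transient <- FALSE
  if (biphasic) {
    sr <- second_rise_features(dff, peak_t, k = k, m = m)
    if (!sr$no_second_rise) {
      feats$second_rise_onset_s <- sr$onset_s
      feats$second_peak_time_s <- sr$peak_time_s
      feats$second_insertion_to_peak_s <- sr$peak_time_s - insertion_s
      feats$second_rise_slope <- sr$slope
    }
  }
  structure(feats, class = "kinetic_features")
}

#' Cohort summary of kinetic features
#'
#' Mean and sample standard deviation (n-1 denominator) of each kinetic
#' feature over a cohort of bouts, shaped as a transient-kinetics summary
#' table: one row per group with insertion-to-peak latency and rise slope
#' (plus second-rise columns when present).
#'
#' @param features list of `kinetic_features` (one per bout).
#' @param group cohort label.
#' @return one-row data frame with `group`, `n`, and `<feature>_mean` /
#'   `<feature>_sd` columns.
#' @export
summarize_cohort <- function(features, group = "cohort") {
  if (length(features) < 2)
    stop("cohort summary requires n >= 2 bouts", call. = FALSE)
  stopifnot(all(vapply(features, inherits, logical(1), "kinetic_features")))
  keys <- c("insertion_to_peak_s", "rise_slope", "post_peak_15s_slope",
            "second_insertion_to_peak_s", "second_rise_slope")
  out <- data.frame(group = group, n = length(features))
  for (key in keys) {
    v <- vapply(features, function(f) f[[key]], numeric(1))
    v <- v[!is.na(v)]
    out[[paste0(key, "_mean")]] <- if (length(v)) mean(v) else NA_real_
    out[[paste0(key, "_sd")]] <- if (length(v) > 1) sd(v) else NA_real_
  }
  out
}
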