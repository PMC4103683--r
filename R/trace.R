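#' Dual-channel ROI trace
#'
#' Container for the raw per-frame mean gray levels of a recording: the
#' G-CaMP (green) and mDsRed (red) ROIs and their matched background ROIs
#' placed on the bacterial lawn.
#'
#' @param time_s strictly increasing times (s), length >= 3.
#' @param green,red cell-ROI mean gray levels.
#' @param green_bg,red_bg background-ROI mean gray levels.
#' @return a data frame of class `dual_channel_trace` with those five columns.
#' @export
dual_channel_trace <- function(time_s, green, red, green_bg, red_bg) {
  n <- length(time_s)
  if (n < 3) stop("trace needs at least 3 samples", call. = FALSE)
  lens <- c(length(green), length(red), length(green_bg), length(red_bg))
  if (any(lens != n))
    stop("all series must have the same length as time_s", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing (first violation at sample ",
         which(diff(time_s) <= 0)[1] + 1L, ")", call. = FALSE)
  if (any(c(green, red, green_bg, red_bg) < 0))
    stop("fluorescence values must be non-negative", call. = FALSE)
  structure(
    data.frame(time_s = time_s, green = green, red = red,
               green_bg = green_bg, red_bg = red_bg),
    class = c("dual_channel_trace", "data.frame"))
}

#' Behavioral event log
#'
#' Named list mapping event names (e.g. `insertion`, `valve_open`,
#' `sperm_release_start`, `sperm_release_end`, `retraction`) to sorted
#' numeric vectors of event times in seconds on the recording clock.
#'
#' @param events named list of numeric time vectors.
#' @return a list of class `event_log`.
#' @export
event_log <- function(events = list()) {
  if (!is.list(events)) stop("events must be a named list", call. = FALSE)
  if (length(events) && is.null(names(events)))
    stop("events must be named", call. = FALSE)
  events <- lapply(events, function(v) sort(as.numeric(v)))
  structure(events, class = "event_log")
}

#' Subtract background fluorescence
#'
#' Per-frame, per-channel subtraction of the background-ROI series from the
#' cell-ROI series. Gray levels are non-negative, so results are clipped at
#' zero; a warning is issued when more than 1% of samples clip.
#'
#' @param trace a [dual_channel_trace()].
#' @return a `dual_channel_trace` with background removed (background columns
#'   set to zero) and attribute `background_subtracted = TRUE`.
#' @export
subtract_background <- function(trace) {
  stopifnot(inherits(trace, "dual_channel_trace"))
  g <- trace$green - trace$green_bg
  r <- trace$red - trace$red_bg
  n_clip <- sum(g < 0) + sum(r < 0)
  if (n_clip > 0.01 * 2 * nrow(trace))
    warning(sprintf("%d of %d background-subtracted samples were negative %s",
                    n_clip, 2L * nrow(trace), "and clipped to 0"),
            call. = FALSE)
  out <- dual_channel_trace(trace$time_s, pmax(g, 0), pmax(r, 0),
                            numeric(nrow(trace)), numeric(nrow(trace)))
  attr(out, "background_subtracted") <- TRUE
  out
}

#' Fit a photobleaching decay curve to the red channel
#'
#' Least-squares fit of `red(t) = amplitude * exp(-t / tau_s) + offset`,
#' the standard mono-exponential bleaching model for a Ca2+-insensitive
#' reference fluorophore. Starting values come from a log-linear regression
#' on the offset-corrected series; the fit is refined with
#' [minpack.lm::nlsLM()].
#'
#' @param red background-subtracted red series (>= 10 samples, not constant
#'   for a proper fit; a constant series returns `amplitude = 0`,
#'   `offset = mean`, `tau_s = NA`).
#' @param time_s matching time vector (s).
#' @return an object of class `bleach_model`: list with `amplitude`, `tau_s`,
#'   `offset`, `rss`.
#' @export
fit_bleach_decay <- function(red, time_s) {
  if (length(red) != length(time_s))
    stop("red and time_s must have equal length", call. = FALSE)
  if (length(red) < 10) stop("need >= 10 samples to fit", call. = FALSE)
  if (sd(red) == 0) {
    return(structure(list(amplitude = 0, tau_s = NA_real_,
                          offset = mean(red), rss = 0),
                     class = "bleach_model"))
  }
  ## initial guesses: offset below the series minimum, log-linear tau
  span <- max(red) - min(red)
  c0 <- min(red) - 0.05 * span
  pos <- red - c0
  lf <- lm(log(pos) ~ time_s)
  tau0 <- -1 / coef(lf)[[2]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(time_s)) / 2
  a0 <- exp(coef(lf)[[1]])
  df <- data.frame(t = time_s, y = red)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-t / tau) + C, data = df,
      start = list(A = a0, tau = tau0, C = c0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e)
      stop("bleach fit did not converge (initial guesses A=", signif(a0, 4),
           ", tau=", signif(tau0, 4), ", C=", signif(c0, 4), "): ",
           conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  structure(list(amplitude = cf[["A"]], tau_s = cf[["tau"]],
                 offset = cf[["C"]], rss = sum(residuals(fit)^2)),
            class = "bleach_model")
}

#' Evaluate a bleach model
#'
#' @param model a `bleach_model`.
#' @param time_s times at which to evaluate the fitted decay.
#' @return fitted red values `amplitude * exp(-t/tau) + offset`.
#' @export
bleach_value <- function(model, time_s) {
  stopifnot(inherits(model, "bleach_model"))
  if (model$amplitude == 0 || is.na(model$tau_s))
    return(rep(model$offset, length(time_s)))
  model$amplitude * exp(-time_s / model$tau_s) + model$offset
}

#' @export
print.bleach_model <- function(x, ...) {
  cat(sprintf("<bleach_model> amplitude %.4g, tau %.4g s, offset %.4g (rss %.4g)\n",
              x$amplitude, x$tau_s, x$offset, x$rss))
  invisible(x)
}

#' Remove bleaching from the red channel
#'
#' Rescales the red series by the fitted decay so that the corrected series
#' is referenced to the model's t = 0 level:
#' `corrected(t) = red(t) * model(0) / model(t)`. A series exactly equal to
#' the model curve becomes constant at `amplitude + offset`.
#'
#' @param red background-subtracted red series.
#' @param time_s matching times (s).
#' @param model a `bleach_model` fitted on the same time base.
#' @return corrected red series.
#' @export
correct_red <- function(red, time_s, model) {
  m <- bleach_value(model, time_s)
  if (any(m <= 0))
    stop("bleach model is non-positive over the trace; cannot correct",
         call. = FALSE)
  red * bleach_value(model, 0) / m
}

dff_trace <- function(time_s, dff_percent, f0, events = NULL) {
  structure(data.frame(time_s = time_s, dff_percent = dff_percent),
            f0 = f0, events = events,
            class = c("dff_trace", "data.frame"))
}

#' Ratiometric percent dF/F0
#'
#' Forms the green:corrected-red ratio `r(t)`, takes `F0` as the mean ratio
#' over a baseline window preceding the first insertion, and returns
#' `100 * (r(t) - F0) / F0`. By construction the mean dF/F0 over the baseline
#' window is zero.
#'
#' @param trace a background-subtracted [dual_channel_trace()].
#' @param model optional `bleach_model`; fitted on `trace$red` when `NULL`.
#' @param f0_window length-2 numeric `(t_start, t_end)` baseline window, with
#'   >= 5 samples. Default: the 2 s preceding the first `insertion` event
#'   (clipped to the recording start).
#' @param events an [event_log()]; required when `f0_window` is `NULL`.
#' @return a `dff_trace`: data frame `time_s`, `dff_percent`, with attributes
#'   `f0` (baseline green:red ratio) and `events`.
#' @export
ratiometric_dff <- function(trace, model = NULL, f0_window = NULL,
                            events = NULL) {
  stopifnot(inherits(trace, "dual_channel_trace"))
  if (!isTRUE(attr(trace, "background_subtracted")) &&
      any(trace$green_bg > 0 | trace$red_bg > 0))
    stop("background not yet subtracted; call subtract_background() first",
         call. = FALSE)
  if (is.null(model)) model <- fit_bleach_decay(trace$red, trace$time_s)
  red_c <- correct_red(trace$red, trace$time_s, model)
  if (any(red_c <= 0))
    stop("corrected red channel is non-positive; cannot form ratio",
         call. = FALSE)
  ratio <- trace$green / red_c
  .dff_from_series(ratio, trace$time_s, f0_window, events)
}

#' Single-channel percent dF/F0
#'
#' dF/F0 computed directly on one fluorescence channel against its own
#' baseline mean, for restrained single-indicator recordings with no red
#' reference.
#'
#' @param green fluorescence series (background-subtracted).
#' @param time_s matching times (s).
#' @inheritParams ratiometric_dff
#' @return a `dff_trace`.
#' @export
single_channel_dff <- function(green, time_s, f0_window = NULL,
                               events = NULL) {
  if (length(green) != length(time_s))
    stop("green and time_s must have equal length", call. = FALSE)
  .dff_from_series(green, time_s, f0_window, events)
}

.dff_from_series <- function(series, time_s, f0_window, events) {
  if (is.null(f0_window)) {
    ins <- events[["insertion"]]
    if (is.null(ins) || !length(ins))
      stop("f0_window not given and no insertion event to anchor it",
           call. = FALSE)
    f0_window <- c(max(time_s[1], ins[1] - 2), ins[1])
  }
  sel <- time_s >= f0_window[1] & time_s <= f0_window[2]
  if (sum(sel) < 5)
    stop("baseline window [", f0_window[1], ", ", f0_window[2],
         "] contains fewer than 5 samples", call. = FALSE)
  f0 <- mean(series[sel])
  if (f0 <= 0) stop("baseline F0 must be positive", call. = FALSE)
  dff_trace(time_s, 100 * (series - f0) / f0, f0 = f0, events = events)
}

#' Summary statistics for restrained (agonist-exposure) recordings
#'
#' For cover-slip-restrained preparations scored over a fixed observation
#' window: the largest absolute calcium change from time point 0, and the
#' standard deviation of dF/F0 over the window.
#'
#' @param dff a `dff_trace`.
#' @param window_s window length (s) from the first sample.
#' @return list with `max_change_from_t0` and `sd` (both %dF/F0).
#' @export
restrained_summary <- function(dff, window_s = 60) {
  stopifnot(inherits(dff, "dff_trace"))
  t0 <- dff$time_s[1]
  if (t0 + window_s > dff$time_s[nrow(dff)] + 1e-9)
    stop("window of ", window_s, " s extends beyond the trace", call. = FALSE)
  sel <- dff$time_s <= t0 + window_s + 1e-9
  y <- dff$dff_percent[sel]
  list(max_change_from_t0 = max(abs(y - y[1])), sd = sd(y))
}
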