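#' Render a trace as a two-channel image stack
#'
#' Builds per-frame pixel images whose ROI mean reproduces the trace: inside
#' the (possibly drifting) ROI every pixel of channel 1 equals the green
#' trace value at that frame and channel 2 the red value; pixels outside the
#' ROI sit at `background_level`. This provides an image-level fixture for
#' validating ROI extraction round trips; the recording itself supplies only
#' ROI means.
#'
#' @param trace a [dual_channel_trace()].
#' @param roi length-4 numeric `c(cx, cy, width, height)`: ROI center
#'   (0-based pixel coordinates) and size in pixels.
#' @param frame_shape length-2 integer `c(height, width)` in pixels.
#' @param drift optional data frame `frame, cx, cy` overriding the ROI
#'   center per frame (0-based frame index); an empty drift path keeps the
#'   ROI static.
#' @param background_level gray level outside the ROI.
#' @return list of class `image_stack`: `frames` (array
#'   `n x height x width x 2`) and `roi_track` (data frame
#'   `frame, cx, cy, width, height`).
#' @export
render_frames <- function(trace, roi, frame_shape = c(32, 32), drift = NULL,
                          background_level = 50) {
  stopifnot(inherits(trace, "dual_channel_trace"))
  n <- nrow(trace)
  h <- frame_shape[1]; w <- frame_shape[2]
  cx <- rep(roi[1], n); cy <- rep(roi[2], n)
  if (!is.null(drift) && nrow(drift)) {
    idx <- drift$frame + 1L
    cx[idx] <- drift$cx; cy[idx] <- drift$cy
  }
  rw <- roi[3]; rh <- roi[4]
  x0 <- round(cx - rw / 2); y0 <- round(cy - rh / 2)
  if (any(x0 < 0 | y0 < 0 | x0 + rw > w | y0 + rh > h))
    stop("ROI exits the frame", call. = FALSE)
  frames <- array(background_level, dim = c(n, h, w, 2))
  for (i in seq_len(n)) {
    rows <- (y0[i] + 1):(y0[i] + rh)
    cols <- (x0[i] + 1):(x0[i] + rw)
    frames[i, rows, cols, 1] <- trace$green[i]
    frames[i, rows, cols, 2] <- trace$red[i]
  }
  track <- data.frame(frame = seq_len(n) - 1L, cx = cx, cy = cy,
                      width = rw, height = rh)
  structure(list(frames = frames, roi_track = track,
                 background_level = background_level,
                 time_s = trace$time_s),
            class = "image_stack")
}

#' Extract ROI mean gray levels from an image stack
#'
#' Mean pixel value inside the tracked ROI, per frame and channel, plus a
#' background ROI of the same size anchored at a fixed position. Returns the
#' same container the analysis pipeline starts from, so
#' `extract_roi_means(render_frames(x))` reproduces `x` for a correctly
#' tracked ROI.
#'
#' @param stack an `image_stack` from [render_frames()].
#' @param roi_track data frame `frame, cx, cy, width, height`; defaults to
#'   the stack's own track. Supplying a stale (non-moving) track measures
#'   the cost of losing the cell.
#' @param bg_origin length-2 `c(cx, cy)` center of the background ROI
#'   (default: top-left corner area).
#' @return a [dual_channel_trace()].
#' @export
extract_roi_means <- function(stack, roi_track = NULL, bg_origin = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  track <- if (is.null(roi_track)) stack$roi_track else roi_track
  n <- dim(stack$frames)[1]
  h <- dim(stack$frames)[2]; w <- dim(stack$frames)[3]
  if (is.null(bg_origin))
    bg_origin <- c(track$width[1] / 2, track$height[1] / 2)
  g <- r <- gb <- rb <- numeric(n)
  for (i in seq_len(n)) {
    rw <- track$width[i]; rh <- track$height[i]
    x0 <- round(track$cx[i] - rw / 2); y0 <- round(track$cy[i] - rh / 2)
    if (x0 < 0 || y0 < 0 || x0 + rw > w || y0 + rh > h)
      stop("ROI track exits the frame at frame ", i - 1L, call. = FALSE)
    rows <- (y0 + 1):(y0 + rh); cols <- (x0 + 1):(x0 + rw)
    g[i] <- mean(stack$frames[i, rows, cols, 1])
    r[i] <- mean(stack$frames[i, rows, cols, 2])
    bx0 <- round(bg_origin[1] - rw / 2); by0 <- round(bg_origin[2] - rh / 2)
    brows <- (max(by0, 0) + 1):(max(by0, 0) + rh)
    bcols <- (max(bx0, 0) + 1):(max(bx0, 0) + rw)
    gb[i] <- mean(stack$frames[i, brows, bcols, 1])
    rb[i] <- mean(stack$frames[i, brows, bcols, 2])
  }
  dual_channel_trace(stack$time_s, g, r, gb, rb)
}
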