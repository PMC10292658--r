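#' Eye-region geometry for the synthetic video renderer
#'
#' @param width,height frame size in pixels.
#' @param roi eye region as `c(x, y, w, h)` in 0-based, half-open pixel
#'   coordinates (x along columns, y along rows).
#' @param lid_intensity,bg_intensity grey levels of closed-lid and open-eye
#'   pixels inside the ROI, in `[0, 1]`.
#' @param outside_intensity grey level of the face outside the ROI.
#' @param noise_sd per-pixel Gaussian intensity noise SD.
#' @return an `eye_geometry` list.
#' @export
eye_geometry <- function(width = 40L, height = 30L, roi = c(4L, 3L, 32L, 24L),
                         lid_intensity = 0.85, bg_intensity = 0.15,
                         outside_intensity = 0.05, noise_sd = 0.02) {
  stopifnot(length(roi) == 4L, all(roi[3:4] > 0),
            roi[1] >= 0, roi[2] >= 0,
            roi[1] + roi[3] <= width, roi[2] + roi[4] <= height,
            lid_intensity > bg_intensity)
  g <- list(width = as.integer(width), height = as.integer(height),
            roi = as.integer(roi), lid_intensity = lid_intensity,
            bg_intensity = bg_intensity, outside_intensity = outside_intensity,
            noise_sd = noise_sd)
  class(g) <- "eye_geometry"
  g
}

#' Construct a frame stack
#'
#' @param frames numeric array `height x width x n_frames`, grey values in
#'   `[0, 1]`.
#' @param timestamps_ms strictly increasing frame times (ms).
#' @param roi `c(x, y, w, h)`, 0-based half-open, within frame bounds.
#' @return a `frame_stack` object.
#' @export
frame_stack <- function(frames, timestamps_ms, roi) {
  stopifnot(length(dim(frames)) == 3L)
  if (dim(frames)[3] != length(timestamps_ms)) {
    stop_invalid("one timestamp per frame required")
  }
  if (any(diff(timestamps_ms) <= 0)) {
    stop_invalid("timestamps must be strictly increasing")
  }
  roi <- as.integer(roi)
  if (length(roi) != 4L || any(roi[3:4] < 0) || roi[1] < 0 || roi[2] < 0 ||
      roi[1] + roi[3] > dim(frames)[2] || roi[2] + roi[4] > dim(frames)[1]) {
    stop_invalid("`roi` must be c(x, y, w, h) within frame bounds")
  }
  s <- list(frames = frames, timestamps_ms = as.numeric(timestamps_ms), roi = roi)
  class(s) <- "frame_stack"
  s
}

#' Render an eyelid trace as a grayscale video
#'
#' Emulates a camera looking at the eye: within the ROI, the trace value
#' (white-pixel count) determines how many pixels take the bright closed-lid
#' intensity. Pixels are filled in a fixed nested order growing outward from
#' the ROI corner, so the lid region stays compact (it survives spatial
#' smoothing instead of thinning into sub-threshold strips) and the
#' bright-pixel count is a monotone, invertible function of the trace value.
#' Frame timestamps carry the trace's time axis through.
#'
#' @param trace an [eyelid_trace()].
#' @param geometry an [eye_geometry()].
#' @param seed integer seed for the pixel noise.
#' @return a [frame_stack()].
#' @export
render_video <- function(trace, geometry = eye_geometry(), seed = 1L) {
  stopifnot(inherits(trace, "eyelid_trace"), inherits(geometry, "eye_geometry"))
  h <- geometry$height; w <- geometry$width
  roi <- geometry$roi
  roi_rows <- (roi[2] + 1L):(roi[2] + roi[4])
  roi_cols <- (roi[1] + 1L):(roi[1] + roi[3])
  roi_area <- roi[3] * roi[4]
  n <- nrow(trace)
  n_white <- pmin(pmax(round(trace$value_px), 0), roi_area)

  base <- matrix(geometry$outside_intensity, h, w)
  withr::with_seed(as.integer(seed), {
    frames <- array(rep(base, n), dim = c(h, w, n))
    # nested compact fill: pixel rank = order of distance from the ROI corner
    rr <- matrix(seq_len(roi[4]), roi[4], roi[3])
    cc <- matrix(rep(seq_len(roi[3]), each = roi[4]), roi[4], roi[3])
    rank <- integer(roi_area)
    rank[order(sqrt((rr - 1)^2 + (cc - 1)^2), rr, cc)] <- seq_len(roi_area)
    roi_vals <- outer(rank, n_white,
                      function(i, k) ifelse(i <= k, geometry$lid_intensity,
                                            geometry$bg_intensity))
    dim(roi_vals) <- c(roi[4], roi[3], n)
    frames[roi_rows, roi_cols, ] <- roi_vals
    if (geometry$noise_sd > 0) {
      frames <- frames + rnorm(length(frames), 0, geometry$noise_sd)
    }
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
    frame_stack(frames, trace$time_ms, roi)
  })
}
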