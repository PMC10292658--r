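# Separable box smoothing of a frame stack. Implemented as averaging-matrix
# multiplications so a whole stack is smoothed with two matrix products;
# windows are truncated and renormalised at frame edges.
box_average_matrix <- function(n, radius) {
  if (radius == 0) return(diag(n))
  idx <- seq_len(n)
  a <- outer(idx, idx, function(i, j) abs(i - j) <= radius)
  a / rowSums(a)
}

smooth_stack <- function(frames, radius) {
  if (radius == 0) return(frames)
  d <- dim(frames)
  ah <- box_average_matrix(d[1], radius)
  aw <- box_average_matrix(d[2], radius)
  y <- ah %*% matrix(frames, d[1], d[2] * d[3])       # rows (height)
  dim(y) <- d
  y <- aperm(y, c(2L, 1L, 3L))
  y <- aw %*% matrix(y, d[2], d[1] * d[3])            # columns (width)
  dim(y) <- d[c(2L, 1L, 3L)]
  aperm(y, c(2L, 1L, 3L))
}

#' Otsu binarisation threshold of a grayscale frame
#'
#' Thin wrapper around [EBImage::otsu()] on a `[0, 1]` grey matrix; used as
#' the default threshold, computed on the first (habituation) frame.
#'
#' @param frame numeric matrix with values in `[0, 1]`.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(frame) {
  EBImage::otsu(frame, range = c(0, 1))
}

#' Extract an eyelid-closure trace from a video
#'
#' For each frame, the ROI is spatially smoothed with a box filter,
#' binarised at `binarize_threshold`, and the white (>= threshold) pixels are
#' counted; the count tracks total eyelid closure. The time axis is
#' re-referenced so that CS onset is 0.
#'
#' @param stack a [frame_stack()].
#' @param smoothing_radius_px box-filter radius in pixels (window
#'   `2r + 1` square); default 2.
#' @param binarize_threshold intensity threshold in `[0, 1]`; default
#'   (`NULL`) uses Otsu's method on the smoothed ROI of the first frame
#'   (restricting to the ROI keeps dark pixels outside the eye region from
#'   dragging the threshold below the lid/background separation).
#' @param cs_onset_ms CS onset on the stack's timestamp axis.
#' @return an [eyelid_trace()]; the threshold actually used is stored in the
#'   `binarize_threshold` attribute.
#' @export
extract_trace <- function(stack, smoothing_radius_px = 2L,
                          binarize_threshold = NULL, cs_onset_ms = 0) {
  stopifnot(inherits(stack, "frame_stack"))
  roi <- stack$roi
  if (roi[3] == 0L || roi[4] == 0L) stop_invalid("empty roi")
  if (any(diff(stack$timestamps_ms) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  sm <- smooth_stack(stack$frames, as.integer(smoothing_radius_px))
  roi_rows0 <- (roi[2] + 1L):(roi[2] + roi[4])
  roi_cols0 <- (roi[1] + 1L):(roi[1] + roi[3])
  if (is.null(binarize_threshold)) {
    binarize_threshold <- otsu_threshold(sm[roi_rows0, roi_cols0, 1])
  }
  if (binarize_threshold < 0 || binarize_threshold > 1) {
    stop_invalid("`binarize_threshold` must lie in the image intensity range [0, 1]")
  }
  counts <- colSums(sm[roi_rows0, roi_cols0, , drop = FALSE] >= binarize_threshold,
                    dims = 2L)
  tr <- eyelid_trace(stack$timestamps_ms - cs_onset_ms, counts,
                     frame_rate_hz = 1000 / stats::median(diff(stack$timestamps_ms)))
  attr(tr, "binarize_threshold") <- binarize_threshold
  tr
}
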