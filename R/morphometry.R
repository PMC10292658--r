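# count intersections of one segment (a -> a + d) with the circle |p| = r,
# parameterised on t in [0, 1); tangencies count once. Half-open t keeps a
# crossing at a shared vertex from being counted by both adjacent segments.
segment_circle_crossings <- function(ax, ay, dx, dy, r, tol = 1e-9) {
  A <- dx * dx + dy * dy
  B <- 2 * (ax * dx + ay * dy)
  C <- ax * ax + ay * ay - r * r
  n <- length(ax)
  count <- integer(n)
  ok <- A > 0
  disc <- B * B - 4 * A * C
  scale <- B * B + abs(4 * A * C) + 1
  tangent <- ok & abs(disc) <= tol * scale
  two <- ok & disc > tol * scale
  t0 <- ifelse(tangent, -B / (2 * A), NA_real_)
  count[tangent] <- as.integer(t0[tangent] >= 0 & t0[tangent] < 1)
  if (any(two)) {
    sq <- sqrt(pmax(disc[two], 0))
    t1 <- (-B[two] - sq) / (2 * A[two])
    t2 <- (-B[two] + sq) / (2 * A[two])
    count[two] <- (t1 >= 0 & t1 < 1) + (t2 >= 0 & t2 < 1)
  }
  count
}

morph_edges <- function(morph) {
  nodes <- morph$nodes
  child <- nodes[nodes$parent != -1, , drop = FALSE]
  if (nrow(child) == 0) return(NULL)
  j <- match(child$parent, nodes$id)
  data.frame(x0 = nodes$x[j], y0 = nodes$y[j], x1 = child$x, y1 = child$y)
}

#' Sholl profile of a morphology
#'
#' Counts the intersections of the dendritic arbor with concentric circles
#' centred on the soma at `step_um` (default 8 um) radial increments,
#' computed exactly by segment-circle intersection; tangencies count once.
#' Radii run from `step_um` up to the largest multiple of `step_um` not
#' exceeding the arbor's maximal radial extent.
#'
#' @param morph a [neuron_morphology()].
#' @param step_um radial increment (default 8).
#' @param radii_um optional explicit radii overriding the automatic range.
#' @return a `sholl_profile` data frame with `radius_um` and `intersections`.
#' @export
sholl <- function(morph, step_um = 8, radii_um = NULL) {
  stopifnot(inherits(morph, "neuron_morphology"))
  cx <- morph$soma_center[1]; cy <- morph$soma_center[2]
  if (any(!is.finite(c(cx, cy)))) stop_invalid("degenerate soma_center")
  edges <- morph_edges(morph)
  if (is.null(radii_um)) {
    rmax <- if (is.null(edges)) 0 else
      max(sqrt((morph$nodes$x - cx)^2 + (morph$nodes$y - cy)^2))
    radii_um <- if (rmax >= step_um) seq(step_um, step_um * floor(rmax / step_um),
                                         by = step_um) else numeric(0)
  }
  inters <- integer(length(radii_um))
  if (!is.null(edges) && length(radii_um) > 0) {
    ax <- edges$x0 - cx; ay <- edges$y0 - cy
    dx <- edges$x1 - edges$x0; dy <- edges$y1 - edges$y0
    inters <- vapply(radii_um, function(r) {
      sum(segment_circle_crossings(ax, ay, dx, dy, r))
    }, integer(1))
  }
  out <- data.frame(radius_um = radii_um, intersections = inters)
  class(out) <- c("sholl_profile", "data.frame")
  out
}

#' Distal dendritic spine density with every-nth-branchlet sampling
#'
#' With a seeded random starting offset `s` in `{0, ..., stride - 1}`,
#' branchlets `s + 1, s + 1 + stride, ...` (in branchlet order) are sampled;
#' the per-cell density is total spines over total length of the sampled
#' branchlets.
#'
#' @param morph a [neuron_morphology()] whose branchlets carry `n_spines`.
#' @param sampling_stride sample every `sampling_stride`-th branchlet
#'   (default 7).
#' @param seed integer seed for the random starting offset.
#' @return spine density per um, with attributes `sampled_branchlets`,
#'   `total_length_um`, `total_spines`, `start_offset`.
#' @export
spine_density <- function(morph, sampling_stride = 7L, seed = 1L) {
  stopifnot(inherits(morph, "neuron_morphology"))
  b <- morph$branchlets
  if (nrow(b) == 0) stop("morphology has no branchlets")
  if (anyNA(b$n_spines)) stop("branchlet spine counts are missing")
  stride <- as.integer(sampling_stride)
  s <- withr::with_seed(as.integer(seed), sample.int(stride, 1L) - 1L)
  idx <- seq(s + 1L, nrow(b), by = stride)
  dens <- sum(b$n_spines[idx]) / sum(b$length_um[idx])
  structure(dens, sampled_branchlets = b$branchlet_id[idx],
            total_length_um = sum(b$length_um[idx]),
            total_spines = sum(b$n_spines[idx]), start_offset = s)
}

# O(n^2) proper-crossing test between non-adjacent polygon edges
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      d1 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d2 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      d3 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d4 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Soma cross-sectional area
#'
#' Area of the closed soma contour by the shoelace formula
#' ([pracma::polyarea()]).
#'
#' @param morph a [neuron_morphology()].
#' @return area in um^2.
#' @export
soma_area <- function(morph) {
  stopifnot(inherits(morph, "neuron_morphology"))
  ct <- morph$soma_contour
  if (polygon_self_intersects(ct$x, ct$y)) stop("self-intersecting soma contour")
  abs(pracma::polyarea(ct$x, ct$y))
}

#' Maximal dendritic arbor height
#'
#' Maximal perpendicular distance of any branch point from the horizontal
#' axis through the soma centre.
#'
#' @param morph a [neuron_morphology()].
#' @return height in um (0 for an empty arbor).
#' @export
arbor_height <- function(morph) {
  stopifnot(inherits(morph, "neuron_morphology"))
  dend <- morph$nodes[morph$nodes$parent != -1, , drop = FALSE]
  if (nrow(dend) == 0) return(0)
  max(abs(dend$y - morph$soma_center[2]))
}

#' Purkinje-cell linear density
#'
#' Calbindin-positive cells per 100 um of cell-layer midline.
#'
#' @param m data frame (or list) with `n_cells` and `midline_length_um`.
#' @return density in cells per 100 um (vectorised over rows).
#' @export
linear_density <- function(m) {
  if (any(m$midline_length_um <= 0)) stop("midline_length_um must be positive")
  100 * m$n_cells / m$midline_length_um
}

#' Layer thickness by the ribbon approximation
#'
#' A cortical layer of area `A` following a midline of length `L` has mean
#' thickness `A / L`.
#'
#' @param m data frame (or list) with `area_um2` and `midline_length_um`.
#' @return thickness in um (vectorised over rows).
#' @export
layer_thickness <- function(m) {
  if (any(m$midline_length_um <= 0)) stop("midline_length_um must be positive")
  if (any(m$area_um2 < 0)) stop("area_um2 must be nonnegative")
  m$area_um2 / m$midline_length_um
}
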