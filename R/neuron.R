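#' Parameters for the synthetic Purkinje-like morphology generator
#'
#' @param n_primary_branches primary dendrites leaving the soma.
#' @param branch_length_mean_um,branch_length_sd_um per-segment length
#'   distribution (Gaussian, truncated at 2 um).
#' @param branching_depth number of branch orders; each non-terminal segment
#'   bifurcates.
#' @param spine_density_per_um mean spine density; branchlet spine counts are
#'   Poisson with mean density x branchlet length.
#' @param soma_radius_um soma radius (contour is a regular polygon).
#' @param arbor_height_um target maximal height of the arbor above the soma
#'   centre; the tree is scaled isotropically to reach it.
#' @return a `neuron_params` list, validated.
#' @export
neuron_params <- function(n_primary_branches = 2L, branch_length_mean_um = 30,
                          branch_length_sd_um = 10, branching_depth = 5L,
                          spine_density_per_um = 1.5, soma_radius_um = 10,
                          arbor_height_um = 180) {
  p <- list(
    n_primary_branches = as.integer(check_scalar(n_primary_branches,
                                                 "n_primary_branches", 1)),
    branch_length_mean_um = check_scalar(branch_length_mean_um,
                                         "branch_length_mean_um", 0.1),
    branch_length_sd_um = check_scalar(branch_length_sd_um,
                                       "branch_length_sd_um", 0),
    branching_depth = as.integer(check_scalar(branching_depth,
                                              "branching_depth", 1)),
    spine_density_per_um = check_scalar(spine_density_per_um,
                                        "spine_density_per_um", 0),
    soma_radius_um = check_scalar(soma_radius_um, "soma_radius_um", 0.1),
    arbor_height_um = check_scalar(arbor_height_um, "arbor_height_um", 1)
  )
  class(p) <- "neuron_params"
  p
}

#' Construct a planar neuron morphology
#'
#' @param nodes data frame in SWC layout: `id`, `type` (1 soma, 3 dendrite),
#'   `x`, `y`, `z` (0 for planar data), `radius`, `parent` (-1 for the root).
#' @param soma_center numeric `c(x, y)`; defaults to the root node position.
#' @param soma_contour closed planar polygon (data frame with `x`, `y`);
#'   defaults to a 24-gon of the root node's radius.
#' @param branchlet_spines optional data frame `branchlet_id`, `n_spines`
#'   matching the morphology's branchlets (terminal segments).
#' @return a `neuron_morphology` list with `nodes`, `soma_center`,
#'   `soma_contour` and `branchlets` (`branchlet_id`, `length_um`,
#'   `n_spines`).
#' @export
neuron_morphology <- function(nodes, soma_center = NULL, soma_contour = NULL,
                              branchlet_spines = NULL) {
  stopifnot(all(c("id", "type", "x", "y", "parent") %in% names(nodes)))
  if (!"z" %in% names(nodes)) nodes$z <- 0
  if (!"radius" %in% names(nodes)) nodes$radius <- 1
  root <- nodes[nodes$parent == -1, , drop = FALSE]
  if (nrow(root) != 1) stop_invalid("exactly one root node (parent = -1) required")
  if (!all(nodes$parent %in% c(-1, nodes$id))) {
    stop_invalid("every parent must reference an existing node")
  }
  if (is.null(soma_center)) soma_center <- c(root$x, root$y)
  if (any(!is.finite(soma_center)) || length(soma_center) != 2) {
    stop_invalid("degenerate soma_center")
  }
  if (is.null(soma_contour)) {
    th <- seq(0, 2 * pi, length.out = 25L)[-25L]
    soma_contour <- data.frame(x = soma_center[1] + root$radius * cos(th),
                               y = soma_center[2] + root$radius * sin(th))
  }
  m <- list(nodes = nodes, soma_center = as.numeric(soma_center),
            soma_contour = soma_contour)
  m$branchlets <- compute_branchlets(nodes)
  if (!is.null(branchlet_spines)) {
    i <- match(m$branchlets$branchlet_id, branchlet_spines$branchlet_id)
    if (anyNA(i)) stop_invalid("branchlet_spines does not cover all branchlets")
    m$branchlets$n_spines <- branchlet_spines$n_spines[i]
  }
  class(m) <- "neuron_morphology"
  m
}

# terminal segments: path from each leaf back to the first branch point
# (node with >= 2 children) or the root; ordered by leaf id
compute_branchlets <- function(nodes) {
  if (nrow(nodes) <= 1) {
    return(data.frame(branchlet_id = integer(0), leaf_id = integer(0),
                      length_um = numeric(0), n_spines = NA_integer_[0]))
  }
  n_children <- table(factor(nodes$parent, levels = nodes$id))
  kids <- as.integer(n_children[as.character(nodes$id)])
  leaves <- nodes$id[kids == 0 & nodes$parent != -1]
  idx <- setNames(seq_len(nrow(nodes)), nodes$id)
  lens <- vapply(sort(leaves), function(leaf) {
    len <- 0
    cur <- leaf
    repeat {
      i <- idx[[as.character(cur)]]
      p <- nodes$parent[i]
      j <- idx[[as.character(p)]]
      len <- len + sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2)
      if (nodes$parent[j] == -1 || kids[j] >= 2) break
      cur <- p
    }
    len
  }, numeric(1))
  data.frame(branchlet_id = seq_along(lens), leaf_id = sort(leaves),
             length_um = as.numeric(lens), n_spines = NA_integer_)
}

#' Generate a seeded synthetic Purkinje-like morphology
#'
#' Grows a planar binary tree rooted at the soma centre: primary branches
#' leave the soma pointing upward with angular spread, every segment has a
#' Gaussian length, and each non-terminal segment bifurcates with jittered
#' angles until `branching_depth` orders. The tree is scaled isotropically
#' so the tallest point sits `arbor_height_um` above the soma centre, then
#' branchlet spine counts are drawn Poisson with mean
#' `spine_density_per_um` x branchlet length.
#'
#' @param params a [neuron_params()] object.
#' @param seed integer seed.
#' @return a [neuron_morphology()].
#' @export
generate_morphology <- function(params = neuron_params(), seed = 1L) {
  stopifnot(inherits(params, "neuron_params"))
  withr::with_seed(as.integer(seed), {
    nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                        radius = params$soma_radius_um, parent = -1L)
    next_id <- 2L
    grow <- function(parent_id, px, py, angle, depth) {
      len <- max(2, rnorm(1, params$branch_length_mean_um,
                          params$branch_length_sd_um))
      x <- px + len * cos(angle)
      y <- py + len * sin(angle)
      id <- next_id
      next_id <<- next_id + 1L
      nodes[nrow(nodes) + 1L, ] <<- list(id, 3L, x, y, 0, 0.5, parent_id)
      if (depth < params$branching_depth) {
        spread <- runif(2, 10, 35) * pi / 180
        grow(id, x, y, angle + spread[1], depth + 1L)
        grow(id, x, y, angle - spread[2], depth + 1L)
      }
    }
    n_prim <- params$n_primary_branches
    base_angles <- seq(65, 115, length.out = max(n_prim, 2)) * pi / 180
    if (n_prim == 1) base_angles <- pi / 2
    for (a in base_angles[seq_len(n_prim)]) {
      grow(1L, 0, 0, a + runif(1, -0.1, 0.1), 1L)
    }
    ymax <- max(nodes$y)
    if (ymax > 0) {
      s <- params$arbor_height_um / ymax
      nodes$x <- nodes$x * s
      nodes$y <- nodes$y * s
    }
    m <- neuron_morphology(nodes)
    m$branchlets$n_spines <- rpois(nrow(m$branchlets),
                                   params$spine_density_per_um *
                                     m$branchlets$length_um)
    m
  })
}
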