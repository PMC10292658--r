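test_that("a straight 41 um radial branch crosses five circles once each", {
  m <- straight_branch_morphology(41)
  pr <- sholl(m)
  expect_equal(pr$radius_um, c(8, 16, 24, 32, 40))
  expect_equal(pr$intersections, rep(1L, 5))
  # same geometry split into several collinear nodes
  m4 <- straight_branch_morphology(41, n_nodes = 4L)
  expect_equal(sholl(m4)$intersections, rep(1L, 5))
})

test_that("an empty arbor yields an all-zero profile", {
  soma_only <- neuron_morphology(data.frame(id = 1, type = 1, x = 0, y = 0,
                                            z = 0, radius = 5, parent = -1))
  pr <- sholl(soma_only)
  expect_true(all(pr$intersections == 0))
})

test_that("Sholl profiles match the dense-resampling oracle on random trees", {
  for (s in 1:20) {
    m <- generate_morphology(neuron_params(branching_depth = 4), seed = s)
    pr <- sholl(m)
    expect_equal(pr$intersections,
                 oracle_sholl_counts(m, pr$radius_um),
                 info = paste("seed", s))
  }
})

test_that("Sholl profiles are invariant under rigid rotation", {
  m <- generate_morphology(neuron_params(), seed = 42)
  th <- 0.83
  rot <- m
  rot$nodes$x <- m$nodes$x * cos(th) - m$nodes$y * sin(th)
  rot$nodes$y <- m$nodes$x * sin(th) + m$nodes$y * cos(th)
  expect_equal(sholl(m)$intersections, sholl(rot)$intersections)
})

test_that("spine density divides sampled spines by sampled length", {
  nodes <- data.frame(id = 1:2, type = c(1, 3), x = c(0, 20), y = 0, z = 0,
                      radius = c(5, 0.5), parent = c(-1, 1))
  m <- neuron_morphology(nodes, branchlet_spines = data.frame(
    branchlet_id = 1, n_spines = 14))
  expect_equal(as.numeric(spine_density(m, seed = 1)), 0.7)
})

test_that("homogeneous density is recovered exactly for every stride start", {
  m <- generate_morphology(neuron_params(branching_depth = 5), seed = 3)
  m$branchlets$n_spines <- 0.5 * m$branchlets$length_um  # exact homogeneity
  dens <- vapply(1:50, function(s) as.numeric(spine_density(m, 7, seed = s)),
                 numeric(1))
  expect_equal(dens, rep(0.5, 50))
  starts <- vapply(1:50, function(s) attr(spine_density(m, 7, seed = s),
                                          "start_offset"), integer(1))
  expect_gt(length(unique(starts)), 1)  # the offset really is randomized
})

test_that("zero spine density yields all-zero branchlet counts", {
  m <- generate_morphology(neuron_params(spine_density_per_um = 0), seed = 9)
  expect_true(all(m$branchlets$n_spines == 0))
})

test_that("Poisson-generated spine density is recovered within 3 SEs", {
  m <- generate_morphology(neuron_params(branching_depth = 8,
                                         spine_density_per_um = 1.0,
                                         arbor_height_um = 220), seed = 7)
  d <- spine_density(m, 7, seed = 11)
  L <- attr(d, "total_length_um")
  expect_gte(L, 500)
  se <- sqrt(1.0 / L)  # Poisson sampling error of the pooled estimate
  expect_lt(abs(as.numeric(d) - 1.0), 3 * se)
})

test_that("soma area and arbor height have exact analytic cases", {
  sq <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  nodes <- data.frame(id = 1:2, type = c(1, 3), x = 0, y = c(0, 150), z = 0,
                      radius = c(5, 0.5), parent = c(-1, 1))
  m <- neuron_morphology(nodes, soma_center = c(5, 0), soma_contour = sq)
  expect_equal(soma_area(m), 100)
  expect_equal(arbor_height(m), 150)
  bow <- data.frame(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  m_bad <- neuron_morphology(nodes, soma_center = c(5, 0), soma_contour = bow)
  expect_error(soma_area(m_bad), "self-intersecting")
})

test_that("random convex polygon area matches a Monte-Carlo estimate", {
  pts <- withr::with_seed(5, cbind(runif(40, 0, 30), runif(40, 0, 30)))
  hull <- pts[chull(pts), ]
  nodes <- data.frame(id = 1:2, type = c(1, 3), x = c(15, 15), y = c(15, 40),
                      z = 0, radius = c(5, 0.5), parent = c(-1, 1))
  m <- neuron_morphology(nodes, soma_center = c(15, 15),
                         soma_contour = data.frame(x = hull[, 1], y = hull[, 2]))
  mc <- withr::with_seed(6, {
    px <- runif(5e5, 0, 30); py <- runif(5e5, 0, 30)
    900 * mean(pracma::inpolygon(px, py, hull[, 1], hull[, 2]))
  })
  expect_lt(abs(soma_area(m) - mc) / mc, 0.005)
})

test_that("linear density and layer thickness follow their ratios", {
  m <- data.frame(lobule_id = c("I/II", "VI"), n_cells = c(30, 0),
                  midline_length_um = c(1200, 900),
                  area_um2 = c(50000, 45000))
  expect_equal(linear_density(m), c(2.5, 0))
  expect_equal(layer_thickness(data.frame(area_um2 = 50000,
                                          midline_length_um = 1000)), 50)
  # doubling both area and length leaves thickness unchanged
  expect_equal(layer_thickness(data.frame(area_um2 = 1e5,
                                          midline_length_um = 2000)), 50)
  expect_error(linear_density(data.frame(n_cells = 1, midline_length_um = 0)),
               "positive")
})

test_that("density gradients across lobules keep their ordering", {
  truth <- seq(1.5, 4.3, length.out = 8)
  lob <- withr::with_seed(8, data.frame(
    n_cells = rpois(8, truth * 20),          # ~2000 um of layer each
    midline_length_um = rep(2000, 8)))
  est <- linear_density(lob)
  expect_gt(cor(est, truth, method = "spearman"), 0.8)
})

test_that("a synthetic ribbon of known width recovers that width", {
  # gently curved midline, offset +/- w/2 along the normal
  s <- seq(0, 2000, length.out = 400)
  mid_x <- s; mid_y <- 40 * sin(s / 400)
  dx <- c(diff(mid_x), tail(diff(mid_x), 1))
  dy <- c(diff(mid_y), tail(diff(mid_y), 1))
  nrm <- sqrt(dx^2 + dy^2)
  w <- 50
  upper_x <- mid_x - w / 2 * dy / nrm; upper_y <- mid_y + w / 2 * dx / nrm
  lower_x <- mid_x + w / 2 * dy / nrm; lower_y <- mid_y - w / 2 * dx / nrm
  area <- abs(pracma::polyarea(c(upper_x, rev(lower_x)),
                               c(upper_y, rev(lower_y))))
  midlen <- sum(sqrt(diff(mid_x)^2 + diff(mid_y)^2))
  thick <- layer_thickness(data.frame(area_um2 = area,
                                      midline_length_um = midlen))
  expect_lt(abs(thick - w) / w, 0.02)
})

test_that("morphometry outputs are nonnegative and reproducible", {
  m1 <- generate_morphology(neuron_params(), seed = 21)
  m2 <- generate_morphology(neuron_params(), seed = 21)
  expect_identical(m1, m2)
  expect_true(all(sholl(m1)$intersections >= 0))
  expect_true(all(m1$branchlets$length_um > 0))
  expect_true(all(m1$branchlets$n_spines >= 0))
  expect_gt(soma_area(m1), 0)
  expect_gt(arbor_height(m1), 0)
})
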