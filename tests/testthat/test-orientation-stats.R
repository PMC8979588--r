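test_that("chord orientation folds to azimuth [0,180)", {
  expect_equal(unname(segment_orientation(c(1, 0, 0))), c(0, 0))
  expect_equal(unname(segment_orientation(c(0, -1, 0))), c(90, 0))
  expect_equal(unname(segment_orientation(c(0, 0, 1))), c(0, 90))
  expect_equal(unname(segment_orientation(c(0, 0, -1))), c(0, 90))
  expect_equal(unname(segment_orientation(c(-1, 0, 0))), c(0, 0))
  expect_equal(unname(segment_orientation(c(1, 1, 0)))[1], 45)
  expect_true(all(is.na(segment_orientation(c(0, 0, 0)))))
})

test_that("flipping a segment's vertex order changes no orientation output", {
  set.seed(4)
  for (i in 1:20) {
    v <- rnorm(3)
    expect_equal(segment_orientation(v), segment_orientation(-v))
  }
  m <- build_network(y_branch_snakes(), graph_params())
  os1 <- orientation_summary(m)
  # reverse every segment's vertex order
  m2 <- m
  m2$vertices <- do.call(rbind, lapply(split(m$vertices,
                                             m$vertices$segment_id),
                                       function(d) d[rev(seq_len(nrow(d))), ]))
  os2 <- orientation_summary(m2)
  expect_equal(os1$azimuth_hist, os2$azimuth_hist)
  expect_equal(os1$elevation_hist, os2$elevation_hist)
  expect_equal(os1$sum_vector, os2$sum_vector)
  expect_equal(os1$anisotropy_index, os2$anisotropy_index)
})

test_that("uniformity deviation: exact match 0, one-bin degenerate maximum", {
  flat <- rep(1 / 180, 180)
  expect_equal(uniformity_deviation(flat, "flat"), 0)
  one <- c(1, rep(0, 179))
  expect_equal(uniformity_deviation(one, "flat"), 2 - 2 / 180)
  expect_warning(uniformity_deviation(c(2, 2), "flat"), "normaliz")
  # solid-angle expectation integrates cos(elevation)
  centers <- seq(-89.5, 89.5, by = 1)
  solid <- cos(centers * pi / 180)
  expect_equal(uniformity_deviation(solid / sum(solid), "solid_angle",
                                    bin_centers = centers), 0)
})

test_that("azimuth deviation of many isotropic directions is small", {
  set.seed(31)
  v <- matrix(rnorm(3e4), ncol = 3)
  orn <- t(apply(v, 1, segment_orientation))
  h <- tabulate(pmin(180L, floor(orn[, 1]) + 1L), 180)
  expect_lt(uniformity_deviation(h / sum(h), "flat"), 0.15)
})

test_that("cell center is the mean of segment mean positions", {
  m <- build_network(y_branch_snakes(), graph_params())
  mids <- t(sapply(m$segments$segment_id, function(id)
    colMeans(as.matrix(segment_vertices(m, id)[, c("x", "y", "z")]))))
  expect_equal(unname(cell_center(m)), unname(colMeans(mids)))
})

test_that("outward translocation points chords away from the center", {
  # radial star: four straight snakes pointing out of a common region, with
  # vertex order deliberately mixed (two stored pointing inward)
  mk <- function(id, dir, inward) {
    p <- t(sapply(seq(0.5, 3, length.out = 6), function(r) r * dir))
    if (inward) p <- p[rev(seq_len(nrow(p))), ]
    data.frame(snake_id = id, x = p[, 1], y = p[, 2], z = p[, 3],
               intensity = 1)
  }
  s <- snake_set(rbind(mk(1, c(1, 0, 0), FALSE), mk(2, c(-1, 0, 0), TRUE),
                       mk(3, c(0, 1, 0), FALSE), mk(4, c(0, -1, 0), TRUE)))
  m <- build_network(s, graph_params())
  v <- translocate_outward(m)
  truth <- rbind(c(-1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(1, 0, 0))
  # every outward vector must align with its segment's true radial direction
  dirs <- v / sqrt(rowSums(v^2))
  agree <- sapply(seq_len(nrow(v)), function(k)
    max(truth %*% dirs[k, ]))
  expect_true(all(agree > 0.99))
  # the symmetric star has a near-zero sum vector
  sv <- sum_vector(m)
  expect_lt(sv$anisotropy_index, 1e-6)
})

test_that("radial histograms conserve projected magnitude and localize peaks", {
  v <- rbind(c(2, 0, 0), c(3, 0, 0))              # all along +x
  rh <- radial_histograms(v)
  expect_equal(sum(rh$xy > 0), 1)
  expect_equal(unname(rh$xy[rh$xy > 0]), 5)
  expect_equal(sum(rh$xy), sum(sqrt(v[, 1]^2 + v[, 2]^2)))
  # yz projection of +x vectors is zero everywhere
  expect_equal(sum(rh$yz), 0)
  set.seed(17)
  iso <- matrix(rnorm(3e4), ncol = 3)
  rhi <- radial_histograms(iso)
  expect_lt(max(rhi$xy) / min(rhi$xy), 2)
})

test_that("parallel networks give anisotropy near 1, opposed pairs near 0", {
  # two equal segments on the same line, on opposite sides of the center
  s <- snake_set(rbind(
    data.frame(snake_id = 1, x = seq(1, 3, by = 0.5), y = 0, z = 0,
               intensity = 1),
    data.frame(snake_id = 2, x = seq(-3, -1, by = 0.5), y = 0, z = 0,
               intensity = 1)))
  m <- build_network(s, graph_params())
  expect_lt(sum_vector(m)$anisotropy_index, 1e-9)
  set.seed(12)
  iso_m <- build_network(
    read_snakes(fixture_suite(withr::local_tempdir(), "tiny",
                              seed = 2)$isotropic$snakes),
    graph_params())
  expect_lt(sum_vector(iso_m)$anisotropy_index, 0.12)
})

test_that("rotating the network about z shifts the azimuth histogram circularly", {
  set.seed(19)
  s <- random_snake_set(n_snakes = 8, n_vert = 6, box = 5)
  m <- build_network(s, graph_params(epsilon = 0.2))
  os1 <- orientation_summary(m, azimuth_bins = 18)
  ang <- 40 * pi / 180                            # multiple of 10-degree bins
  rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  m2 <- m
  p <- as.matrix(m$vertices[, c("x", "y", "z")]) %*% t(rot)
  m2$vertices$x <- p[, 1]; m2$vertices$y <- p[, 2]; m2$vertices$z <- p[, 3]
  os2 <- orientation_summary(m2, azimuth_bins = 18)
  shifted <- unname(os2$azimuth_hist)
  expected <- unname(os1$azimuth_hist)[((seq_len(18) - 1 - 4) %% 18) + 1]
  expect_equal(shifted, expected)
  # sum vector rotates with the network
  expect_equal(unname(os2$sum_vector), as.vector(rot %*% os1$sum_vector),
               tolerance = 1e-8)
})
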