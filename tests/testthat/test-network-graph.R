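eps <- graph_params()$epsilon

test_that("an isolated snake yields one segment between two end nodes", {
  s <- snake_set(data.frame(snake_id = 1, x = seq(0, 3, by = 0.5), y = 0,
                            z = 0, intensity = 4))
  m <- build_network(s, graph_params())
  expect_equal(nrow(m$segments), 1)
  expect_equal(sort(m$nodes$degree), c(1, 1))
  expect_equal(m$segments$arc_length, 3)
})

test_that("a snake interior touching another snake's end makes a Y-branch", {
  m <- build_network(y_branch_snakes(eps), graph_params())
  expect_equal(nrow(m$segments), 3)
  expect_equal(sort(m$nodes$degree), c(1, 1, 1, 3))
  expect_equal(unname(node_degree_histogram(m)), 1)
  expect_equal(names(node_degree_histogram(m)), "3")
})

test_that("two snakes crossing at interior vertices make an X-node", {
  m <- build_network(x_cross_snakes(eps), graph_params())
  expect_equal(nrow(m$segments), 4)
  expect_equal(sort(m$nodes$degree), c(1, 1, 1, 1, 4))
})

test_that("cluster partition equals the brute-force single-linkage oracle", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_snake_set(n_snakes = sample(3:7, 1),
                          n_vert = sample(5:12, 1))
    e <- runif(1, 0.1, 0.6)
    m <- build_network(s, graph_params(epsilon = e))
    expected <- cluster_signature(
      brute_force_clusters(as.matrix(s[c("x", "y", "z")]), s$snake_id, e))
    expect_identical(model_cluster_signature(m, s), expected)
  }
})

test_that("node positions are unweighted member centroids", {
  s <- y_branch_snakes(eps)
  m <- build_network(s, graph_params())
  branch <- m$nodes[m$nodes$degree == 3, ]
  mem <- m$members[m$members$node_id == branch$node_id, ]
  df <- as.data.frame(s)
  within_index <- unlist(lapply(rle(df$snake_id)$lengths, seq_len))
  rows <- match(paste(mem$snake_id, mem$vertex_index),
                paste(df$snake_id, within_index))
  expect_equal(branch$x, mean(df$x[rows]))
  expect_equal(branch$y, mean(df$y[rows]))
})

test_that("vertex and arc-length conservation through graph building", {
  set.seed(9)
  s <- random_snake_set(n_snakes = 5, n_vert = 10)
  m <- build_network(s, graph_params(epsilon = 0.25))
  # sum of node degrees = 2 x number of segments
  expect_equal(sum(m$nodes$degree), 2 * nrow(m$segments))
  # arc length conserved up to centroid snapping
  total_in <- sum(vapply(snake_list(s), function(v) arc_length(v), 0))
  total_out <- sum(m$segments$arc_length)
  tol <- 0.25 * nrow(m$nodes) / total_in
  expect_lt(abs(total_out - total_in) / total_in, tol)
})

test_that("result is independent of snake input order", {
  set.seed(5)
  s <- random_snake_set(n_snakes = 6, n_vert = 8)
  m1 <- build_network(s, graph_params(epsilon = 0.3))
  df <- as.data.frame(s)
  perm <- sample(unique(df$snake_id))
  df2 <- do.call(rbind, lapply(perm, function(id) df[df$snake_id == id, ]))
  m2 <- build_network(snake_set(df2), graph_params(epsilon = 0.3))
  expect_equal(m1$nodes$x, m2$nodes$x)
  expect_equal(m1$nodes$degree, m2$nodes$degree)
  expect_equal(m1$segments$node_start, m2$segments$node_start)
  expect_equal(m1$segments$arc_length, m2$segments$arc_length)
})

test_that("rebuilding from the model's own segments reproduces the nodes", {
  m <- build_network(y_branch_snakes(eps), graph_params())
  resn <- m$vertices
  names(resn)[names(resn) == "segment_id"] <- "snake_id"
  m2 <- build_network(snake_set(resn), m$params)
  expect_equal(m2$nodes$x, m$nodes$x, tolerance = 1e-9)
  expect_equal(sort(m2$nodes$degree), sort(m$nodes$degree))
})

test_that("consecutive same-node vertices are contracted (no zero arcs)", {
  # two snakes running within eps of each other over two consecutive
  # vertices: the shared cluster must not create a zero-length segment
  s <- snake_set(rbind(
    data.frame(snake_id = 1, x = c(0, 1, 1.03, 2), y = 0, z = 0,
               intensity = 1),
    data.frame(snake_id = 2, x = c(1, 1.03), y = 0.02, z = 0,
               intensity = 1)))
  m <- build_network(s, graph_params(epsilon = 0.06))
  expect_true(all(m$segments$arc_length > 0))
})

test_that("degree histogram pools Y/X/star classes correctly", {
  # one Y (three snakes at a point) + one X (crossing) far apart
  y <- as.data.frame(y_branch_snakes(eps))
  x <- as.data.frame(x_cross_snakes(eps))
  x$snake_id <- x$snake_id + 10
  x$x <- x$x + 50
  m <- build_network(snake_set(rbind(y, x)), graph_params())
  h <- node_degree_histogram(m)
  expect_equal(unname(h[c("3", "4")]), c(0.5, 0.5))
  # no-branch network warns and returns empty
  iso <- snake_set(data.frame(snake_id = 1, x = 0:3, y = 0, z = 0,
                              intensity = 1))
  expect_warning(h0 <- node_degree_histogram(build_network(iso)), "degree")
  expect_length(h0, 0)
})

test_that("filaments concatenate through degree-2 nodes and partition segments", {
  # two snakes joined end-to-end: one degree-2 node, one filament of 2 segments
  s <- snake_set(rbind(
    data.frame(snake_id = 1, x = seq(0, 2, by = 0.5), y = 0, z = 0,
               intensity = 1),
    data.frame(snake_id = 2, x = seq(2.01, 4, by = 0.5), y = 0, z = 0,
               intensity = 1)))
  m <- build_network(s, graph_params())
  expect_equal(sort(m$nodes$degree), c(1, 1, 2))
  ch <- filaments_from_segments(m)
  expect_length(ch, 1)
  expect_equal(sort(ch[[1]]), m$segments$segment_id)

  # Y-branch: three single-segment filaments
  my <- build_network(y_branch_snakes(eps), graph_params())
  chy <- filaments_from_segments(my)
  expect_length(chy, 3)
  expect_equal(sort(unlist(chy)), my$segments$segment_id)
})

test_that("degenerate graph parameters are rejected", {
  expect_error(graph_params(epsilon = -1), "epsilon")
  s <- snake_set(data.frame(snake_id = numeric(0), x = numeric(0),
                            y = numeric(0), z = numeric(0),
                            intensity = numeric(0)))
  expect_error(build_network(s, graph_params()), "empty")
})
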