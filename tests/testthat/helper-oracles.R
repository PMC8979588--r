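# Independent oracles and fixture builders shared across the suite.

# Brute-force single-linkage closure: full distance matrix, adjacency
# restricted to inter-snake pairs, components by repeated expansion.
# Independent of the package's grid/union-find implementation.
brute_force_clusters <- function(coords, snake_id, eps) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  adj <- d <= eps & outer(snake_id, snake_id, "!=")
  diag(adj) <- FALSE
  label <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(label[i])) next
    cur <- cur + 1L
    frontier <- i
    label[i] <- cur
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & is.na(label))
      label[nb] <- cur
      frontier <- nb
    }
  }
  # only clusters of size >= 2 count as candidate sets
  split(seq_len(n), label)[tabulate(label) >= 2]
}

# partition of vertex indices into clusters, as a canonical string set
cluster_signature <- function(clusters) {
  sort(unname(vapply(clusters, function(ix) paste(sort(ix), collapse = ","),
                     "")))
}

# cluster partition recovered from a built model, in global row indices
model_cluster_signature <- function(model, snakes) {
  df <- as.data.frame(snakes)
  within_index <- unlist(lapply(rle(df$snake_id)$lengths, seq_len))
  key <- paste(df$snake_id, within_index)
  mem <- model$members
  mem$row <- match(paste(mem$snake_id, mem$vertex_index), key)
  by_node <- split(mem$row, mem$node_id)
  cluster_signature(by_node[lengths(by_node) >= 2])
}

# Dense, direct 3D Gaussian convolution with mirror boundary — the oracle
# for blur3d.  O(n^3 k^3); use on small stacks only.
dense_gauss3d <- function(vox, sigmas_xyz) {
  kern1 <- function(sigma) {
    if (sigma <= 0) return(1)
    r <- max(1L, ceiling(3.5 * sigma))
    k <- exp(-(-r:r)^2 / (2 * sigma^2))
    k / sum(k)
  }
  # array is (z, y, x)
  ks <- lapply(c(sigmas_xyz[3], sigmas_xyz[2], sigmas_xyz[1]), kern1)
  d <- dim(vox)
  mirror <- function(j, n) {
    if (j < 1) j <- 2 - j
    if (j > n) j <- 2 * n - j
    min(max(j, 1), n)
  }
  out <- array(0, d)
  rs <- lapply(ks, function(k) (length(k) - 1L) %/% 2L)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    acc <- 0
    for (oz in -rs[[1]]:rs[[1]]) for (oy in -rs[[2]]:rs[[2]])
      for (ox in -rs[[3]]:rs[[3]]) {
        acc <- acc + ks[[1]][oz + rs[[1]] + 1] * ks[[2]][oy + rs[[2]] + 1] *
          ks[[3]][ox + rs[[3]] + 1] *
          vox[mirror(z + oz, d[1]), mirror(y + oy, d[2]), mirror(x + ox, d[3])]
      }
    out[z, y, x] <- acc
  }
  out
}

# analytic curve fixtures
circle_polyline <- function(radius, n = 200, arc = pi / 2) {
  th <- seq(0, arc, length.out = n)
  cbind(radius * cos(th), radius * sin(th), 0)
}

helix_polyline <- function(r, c, turns = 2, n = 600) {
  t <- seq(0, 2 * pi * turns, length.out = n)
  cbind(r * cos(t), r * sin(t), c * t)
}

straight_polyline <- function(len = 5, n = 50) {
  cbind(seq(0, len, length.out = n), 0, 0)
}

# random snake sets for the clustering oracle: several short jagged snakes
# in a small box so that inter-snake contacts are frequent
random_snake_set <- function(n_snakes = 6, n_vert = 8, box = 2, jitter = 0.3) {
  dfs <- lapply(seq_len(n_snakes), function(id) {
    start <- runif(3) * box
    steps <- matrix(rnorm(3 * (n_vert - 1), sd = jitter), ncol = 3)
    p <- rbind(start, start + apply(steps, 2, cumsum))
    data.frame(snake_id = id, x = p[, 1], y = p[, 2], z = p[, 3],
               intensity = runif(n_vert, 1, 10))
  })
  snake_set(do.call(rbind, dfs))
}

# random rigid isometry (rotation + translation)
random_isometry <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t <- rnorm(3, sd = 5)
  function(p) sweep(p %*% q, 2, -t)
}

y_branch_snakes <- function(eps = 0.0715) {
  snake_set(rbind(
    data.frame(snake_id = 1, x = seq(0, 4, by = 0.5), y = 0, z = 0,
               intensity = 10),
    data.frame(snake_id = 2, x = 2, y = c(2, 1, eps * 0.4), z = 0,
               intensity = 20)))
}

x_cross_snakes <- function(eps = 0.0715) {
  snake_set(rbind(
    data.frame(snake_id = 1, x = seq(-2, 2, by = 0.5), y = 0, z = 0,
               intensity = 5),
    data.frame(snake_id = 2, x = 0, y = seq(-2, 2, by = 0.5), z = eps * 0.5,
               intensity = 9)))
}

# write lines to a fresh temp file inside dir and return the path
writeLines_tmp <- function(lines, dir) {
  f <- tempfile(tmpdir = dir, fileext = ".yaml")
  writeLines(lines, f)
  f
}
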