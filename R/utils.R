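`%||%` <- function(a, b) if (is.null(a)) b else a

## Euclidean norms of the rows of a 3-column matrix
row_norms <- function(m) sqrt(rowSums(m * m))

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

## Merge all pairs (two-column integer matrix) with union-find (path
## compression) and return component labels in 1..n.
union_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L])
      b <- find(pairs[k, 2L])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1))
}

## All index pairs (i < j) with Euclidean distance <= eps and group[i] !=
## group[j], found with a uniform grid of cell size eps so that only the 27
## neighbouring cells need to be scanned.  Returns a 2-column integer matrix.
proximity_pairs <- function(coords, eps, group) {
  n <- nrow(coords)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cell <- floor(sweep(coords, 2L, apply(coords, 2L, min)) / eps)
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
  by_cell <- split(seq_len(n), key)
  cell_of <- match(key, names(by_cell))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- vector("list", length(by_cell) * nrow(offsets))
  m <- 0L
  for (ci in seq_along(by_cell)) {
    idx_a <- by_cell[[ci]]
    base <- cell[idx_a[1L], ]
    for (oi in seq_len(nrow(offsets))) {
      nb_key <- paste(base[1L] + offsets[oi, 1L],
                      base[2L] + offsets[oi, 2L],
                      base[3L] + offsets[oi, 3L])
      idx_b <- by_cell[[nb_key]]
      if (is.null(idx_b)) next
      ## visit each unordered cell pair once
      if (ci > match(nb_key, names(by_cell))) next
      same_cell <- identical(idx_a, idx_b)
      cand <- expand.grid(i = idx_a, j = idx_b)
      if (same_cell) cand <- cand[cand$i < cand$j, , drop = FALSE]
      if (!nrow(cand)) next
      keep <- group[cand$i] != group[cand$j]
      cand <- cand[keep, , drop = FALSE]
      if (!nrow(cand)) next
      d2 <- rowSums((coords[cand$i, , drop = FALSE] -
                     coords[cand$j, , drop = FALSE])^2)
      cand <- cand[d2 <= eps^2, , drop = FALSE]
      if (nrow(cand)) {
        m <- m + 1L
        out[[m]] <- as.matrix(cand)
      }
    }
  }
  if (m == 0L) return(matrix(integer(0), ncol = 2L))
  res <- do.call(rbind, out[seq_len(m)])
  ## orient pairs i < j and drop duplicates from symmetric cell visits
  res <- cbind(pmin(res[, 1L], res[, 2L]), pmax(res[, 1L], res[, 2L]))
  unique(res)
}

## Uniform random unit vectors in 3D
random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3L * n), ncol = 3L)
  v / row_norms(v)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
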