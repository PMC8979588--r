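#' Graph-construction parameters
#'
#' The clustering radius epsilon defaults to 1.1 times the reference voxel
#' size, the rule used to associate snake vertices into network nodes.  The
#' reference voxel should be the largest in-plane voxel edge of the source
#' recording.
#'
#' @param epsilon clustering radius in micrometres; vertices of different
#'   snakes closer than this are merged into one node.
#' @param reference_voxel reference voxel size in micrometres used for the
#'   default epsilon.
#' @return A list of class `graph_params`.
#' @export
graph_params <- function(epsilon = NULL, reference_voxel = 0.065) {
  stopifnot_scalar(reference_voxel, "reference_voxel")
  if (is.null(epsilon)) epsilon <- 1.1 * reference_voxel
  stopifnot_scalar(epsilon, "epsilon")
  structure(list(epsilon = epsilon, reference_voxel = reference_voxel),
            class = "graph_params")
}

#' Build the node/segment network model from snakes
#'
#' Converts raw snakes into a coherent Euclidean 3D network map:
#'
#' 1. Vertices of *different* snakes within `epsilon` of each other seed
#'    candidate sets that are grown transitively (single linkage): any vertex
#'    at most epsilon from a member of the set joins it, until closure.
#'    Intra-snake pairs are excluded throughout — consecutive polyline
#'    vertices are always within epsilon, so including them would dissolve
#'    every snake into a single node.
#' 2. Each closed candidate set becomes one node at the unweighted centroid
#'    of its member vertices.
#' 3. Every snake is split at its node-member vertices into segments; snake
#'    start and end vertices are always nodes (singleton nodes when they
#'    joined no cluster).
#' 4. Consecutive vertices of one snake assigned to the same node are
#'    contracted so no zero-length segment arises.
#' 5. Segment end vertices are snapped to their node centroid; interior
#'    vertices keep their raw geometry.  Node degree is the number of
#'    incident segment endpoints.
#'
#' Node and segment ids are relabelled canonically (nodes sorted by
#' centroid), so the result is independent of snake input order.
#'
#' @param snakes a [snake_set] with at least one snake.
#' @param params a [graph_params].
#' @param cell_id label stored in the model.
#' @return An object of class `filament_network` with elements `nodes`
#'   (node_id, x, y, z, degree), `members` (node_id, snake_id, vertex_index),
#'   `segments` (segment_id, node_start, node_end, snake_id, n_vertices,
#'   arc_length, mean_intensity), `vertices` (segment_id, x, y, z,
#'   intensity) and `params`.
#' @export
build_network <- function(snakes, params = graph_params(), cell_id = "cell") {
  if (!inherits(snakes, "snake_set")) snakes <- snake_set(snakes)
  if (!nrow(snakes)) stop("empty snake set", call. = FALSE)
  eps <- params$epsilon
  stopifnot_scalar(eps, "epsilon")

  df <- as.data.frame(snakes)
  coords <- as.matrix(df[c("x", "y", "z")])
  n <- nrow(coords)
  snake_ids <- df$snake_id
  within_index <- unlist(lapply(rle(snake_ids)$lengths, seq_len),
                         use.names = FALSE)

  ## single-linkage closure restricted to inter-snake pairs
  pairs <- proximity_pairs(coords, eps, snake_ids)
  comp <- union_components(n, pairs)
  comp_size <- tabulate(comp, nbins = n)
  in_cluster <- comp_size[comp] >= 2L

  ## provisional node label per vertex: cluster component, or a fresh
  ## singleton for snake start/end vertices outside any cluster
  node_of <- ifelse(in_cluster, comp, NA_integer_)
  ends <- which(within_index == 1L | c(diff(snake_ids) != 0, TRUE))
  lone_ends <- ends[!in_cluster[ends]]
  node_of[lone_ends] <- n + seq_along(lone_ends)

  used <- sort(unique(node_of[!is.na(node_of)]))
  node_of <- match(node_of, used)
  n_nodes <- length(used)

  ## centroids over member vertices
  cx <- vapply(seq_len(n_nodes), function(k) mean(coords[which(node_of == k), 1L]), 0)
  cy <- vapply(seq_len(n_nodes), function(k) mean(coords[which(node_of == k), 2L]), 0)
  cz <- vapply(seq_len(n_nodes), function(k) mean(coords[which(node_of == k), 3L]), 0)

  ## split each snake at node-member vertices
  seg_rows <- list(); seg_meta <- list(); m <- 0L
  start_row <- which(within_index == 1L)
  end_row <- c(start_row[-1L] - 1L, n)
  for (s in seq_along(start_row)) {
    rows <- start_row[s]:end_row[s]
    a <- node_of[rows]
    b <- which(!is.na(a))                      # local boundary indices
    for (j in seq_len(length(b) - 1L)) {
      i1 <- b[j]; i2 <- b[j + 1L]
      n1 <- a[i1]; n2 <- a[i2]
      if (i2 == i1 + 1L && n1 == n2) next     # contracted zero-length piece
      idx <- rows[i1:i2]
      v <- df[idx, c("x", "y", "z", "intensity")]
      v[1L, c("x", "y", "z")] <- c(cx[n1], cy[n1], cz[n1])
      v[nrow(v), c("x", "y", "z")] <- c(cx[n2], cy[n2], cz[n2])
      m <- m + 1L
      seg_rows[[m]] <- v
      seg_meta[[m]] <- data.frame(node_start = n1, node_end = n2,
                                  snake_id = snake_ids[rows[1L]],
                                  first_index = i1, last_index = i2)
    }
  }
  if (m == 0L)
    stop("no segments could be formed (all snakes collapsed into nodes)",
         call. = FALSE)
  meta <- do.call(rbind, seg_meta)

  ## canonical node order: lexicographic by centroid
  node_rank <- order(cx, cy, cz)
  relabel <- integer(n_nodes); relabel[node_rank] <- seq_len(n_nodes)
  meta$node_start <- relabel[meta$node_start]
  meta$node_end <- relabel[meta$node_end]
  node_of <- relabel[node_of]
  nodes <- data.frame(node_id = seq_len(n_nodes),
                      x = cx[node_rank], y = cy[node_rank], z = cz[node_rank])

  ## canonical segment order: endpoints (undirected), then geometry
  lo <- pmin(meta$node_start, meta$node_end)
  hi <- pmax(meta$node_start, meta$node_end)
  arc <- vapply(seg_rows, function(v) sum(row_norms(diff(as.matrix(v[1:3])))), 0)
  mint <- vapply(seg_rows, function(v) mean(v$intensity), 0)
  nv <- vapply(seg_rows, nrow, 0L)
  mid <- t(vapply(seg_rows, function(v) colMeans(as.matrix(v[1:3])), numeric(3)))
  seg_rank <- order(lo, hi, arc, mid[, 1L], mid[, 2L], mid[, 3L], mint)

  segments <- data.frame(segment_id = seq_len(m),
                         node_start = meta$node_start[seg_rank],
                         node_end = meta$node_end[seg_rank],
                         snake_id = meta$snake_id[seg_rank],
                         n_vertices = nv[seg_rank],
                         arc_length = arc[seg_rank],
                         mean_intensity = mint[seg_rank])
  vertices <- do.call(rbind, lapply(seq_len(m), function(k) {
    v <- seg_rows[[seg_rank[k]]]
    cbind(segment_id = k, v)
  }))
  rownames(vertices) <- NULL

  degree <- tabulate(c(segments$node_start, segments$node_end),
                     nbins = n_nodes)
  nodes$degree <- degree

  members <- data.frame(node_id = node_of[!is.na(node_of)],
                        snake_id = snake_ids[!is.na(node_of)],
                        vertex_index = within_index[!is.na(node_of)])
  members <- members[order(members$node_id, members$snake_id,
                           members$vertex_index), ]
  rownames(members) <- NULL

  structure(list(cell_id = cell_id, nodes = nodes, members = members,
                 segments = segments, vertices = vertices, params = params),
            class = "filament_network")
}

#' @export
print.filament_network <- function(x, ...) {
  cat(sprintf(
    "<filament_network> '%s': %d nodes, %d segments, %.2f um total length\n",
    x$cell_id, nrow(x$nodes), nrow(x$segments), sum(x$segments$arc_length)))
  cat(sprintf("  epsilon = %.4g um; branching nodes (degree >= 3): %d\n",
              x$params$epsilon, sum(x$nodes$degree >= 3)))
  invisible(x)
}

#' Vertex rows of one segment
#' @param model a `filament_network`.
#' @param segment_id segment id.
#' @return Data frame with columns `x`, `y`, `z`, `intensity` in chain order.
#' @export
segment_vertices <- function(model, segment_id) {
  v <- model$vertices[model$vertices$segment_id == segment_id,
                      c("x", "y", "z", "intensity")]
  rownames(v) <- NULL
  v
}

#' Branching-degree histogram over nodes of degree >= 3
#'
#' The segment/node ratio classifies branchings: 3 incident segments form a
#' Y-branch, 4 an X-crossing, 5 or more a star.  End (degree-1) and
#' pass-through (degree-2) nodes are not branchings and are excluded.
#'
#' @param model a `filament_network`.
#' @return Named numeric vector of relative frequencies (names = degree),
#'   summing to 1; empty (with a warning) when no node branches.
#' @export
node_degree_histogram <- function(model) {
  deg <- model$nodes$degree[model$nodes$degree >= 3L]
  if (!length(deg)) {
    warning("no nodes with degree >= 3")
    return(setNames(numeric(0), character(0)))
  }
  tab <- table(deg)
  setNames(as.numeric(tab) / length(deg), names(tab))
}

#' Concatenate segments through degree-2 nodes into maximal filaments
#'
#' Keratin filaments consist of multiple consecutive segments; this walks
#' through every pass-through (degree-2) node and joins its two incident
#' segments, yielding maximal chains that partition the segment set.
#'
#' @param model a `filament_network`.
#' @return List of integer vectors of segment ids, each a maximal chain.
#' @export
filaments_from_segments <- function(model) {
  segs <- model$segments
  n_nodes <- nrow(model$nodes)
  ## incidences per node
  inc <- vector("list", n_nodes)
  for (k in seq_len(nrow(segs))) {
    inc[[segs$node_start[k]]] <- c(inc[[segs$node_start[k]]], k)
    inc[[segs$node_end[k]]] <- c(inc[[segs$node_end[k]]], k)
  }
  degree <- model$nodes$degree
  pass <- function(node) degree[node] == 2L
  visited <- logical(nrow(segs))
  chains <- list()
  other_end <- function(k, node)
    if (segs$node_start[k] == node) segs$node_end[k] else segs$node_start[k]
  for (k0 in seq_len(nrow(segs))) {
    if (visited[k0]) next
    chain <- k0; visited[k0] <- TRUE
    for (side in 1:2) {
      node <- if (side == 1) segs$node_end[k0] else segs$node_start[k0]
      k <- k0
      while (pass(node)) {
        nxt <- setdiff(inc[[node]], k)
        if (length(nxt) != 1L || visited[nxt]) break
        k <- nxt; visited[k] <- TRUE
        chain <- if (side == 1) c(chain, k) else c(k, chain)
        node <- other_end(k, node)
      }
    }
    chains[[length(chains) + 1L]] <- chain
  }
  chains
}
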