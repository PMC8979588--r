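#' Write a network model to disk
#'
#' Three formats:
#'
#' * `"json"` — lossless: all tables including every vertex and intensity;
#'   [read_network()] restores the model exactly (up to float formatting).
#' * `"graphml"` — an undirected multigraph with node positions and
#'   per-segment summary attributes (length, brightness, vertex count),
#'   readable by igraph, Gephi or Cytoscape.  Vertex chains are summarized,
#'   not embedded.
#' * `"csv_tables"` — three CSV files (`<path>_nodes.csv`,
#'   `<path>_segments.csv`, `<path>_vertices.csv`).
#'
#' @param model a `filament_network`.
#' @param path output file (json/graphml) or path prefix (csv_tables).
#' @param format one of `"json"`, `"graphml"`, `"csv_tables"`.
#' @return The written path(s), invisibly.
#' @export
write_network <- function(model, path,
                          format = c("json", "graphml", "csv_tables")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(cell_id = model$cell_id,
                    params = unclass(model$params),
                    nodes = model$nodes, members = model$members,
                    segments = model$segments, vertices = model$vertices)
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
    return(invisible(path))
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(model$segments$node_start),
                     to = as.character(model$segments$node_end),
                     segment_id = model$segments$segment_id,
                     arc_length = model$segments$arc_length,
                     mean_intensity = model$segments$mean_intensity,
                     n_vertices = model$segments$n_vertices),
      directed = FALSE,
      vertices = data.frame(name = as.character(model$nodes$node_id),
                            x = model$nodes$x, y = model$nodes$y,
                            z = model$nodes$z, degree = model$nodes$degree))
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  paths <- paste0(path, c("_nodes.csv", "_segments.csv", "_vertices.csv"))
  write.csv(model$nodes, paths[1L], row.names = FALSE)
  write.csv(model$segments, paths[2L], row.names = FALSE)
  write.csv(model$vertices, paths[3L], row.names = FALSE)
  invisible(paths)
}

#' Read a JSON network model written by [write_network()]
#'
#' @param path path to the JSON file.
#' @return A `filament_network`.
#' @export
read_network <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- structure(payload$params, class = "graph_params")
  structure(list(cell_id = payload$cell_id,
                 nodes = as.data.frame(payload$nodes),
                 members = as.data.frame(payload$members),
                 segments = as.data.frame(payload$segments),
                 vertices = as.data.frame(payload$vertices),
                 params = params),
            class = "filament_network")
}

## parallel-transport frames along a polyline, for tube tessellation
transport_frames <- function(p) {
  n <- nrow(p)
  tang <- matrix(0, n, 3L)
  tang[1L, ] <- p[2L, ] - p[1L, ]
  tang[n, ] <- p[n, ] - p[n - 1L, ]
  if (n > 2L)
    tang[2:(n - 1L), ] <- (p[3:n, , drop = FALSE] -
                           p[1:(n - 2L), , drop = FALSE]) / 2
  tang <- tang / pmax(row_norms(tang), 1e-12)
  u <- matrix(0, n, 3L); v <- matrix(0, n, 3L)
  ref <- if (abs(tang[1L, 1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u[1L, ] <- ref - sum(ref * tang[1L, ]) * tang[1L, ]
  u[1L, ] <- u[1L, ] / sqrt(sum(u[1L, ]^2))
  for (i in seq_len(n)[-1L]) {
    ui <- u[i - 1L, ] - sum(u[i - 1L, ] * tang[i, ]) * tang[i, ]
    nrm <- sqrt(sum(ui^2))
    if (nrm < 1e-9) ui <- c(1, 0, 0) - tang[i, 1L] * tang[i, ] else ui <- ui / nrm
    u[i, ] <- ui / sqrt(sum(ui^2))
  }
  for (i in seq_len(n))
    v[i, ] <- c(tang[i, 2L] * u[i, 3L] - tang[i, 3L] * u[i, 2L],
                tang[i, 3L] * u[i, 1L] - tang[i, 1L] * u[i, 3L],
                tang[i, 1L] * u[i, 2L] - tang[i, 2L] * u[i, 1L])
  list(u = u, v = v)
}

#' Export a network as OBJ geometry with brightness-proportional thickness
#'
#' Each segment is written as an OBJ polyline (`l` records over its `v`
#' vertices) with a per-segment material (random color, seeded) in a
#' companion `.mtl` file, plus a sidecar CSV mapping each segment to its
#' tube radius `radius_scale * mean segment brightness` — OBJ itself has no
#' portable line-thickness attribute.  With `tubes = TRUE`, tessellated
#' tube meshes (`tube_sides`-sided, parallel-transport frames) are emitted
#' instead of polylines.
#'
#' @param model a `filament_network`.
#' @param path output OBJ path; the MTL and radius sidecar take the same
#'   stem.
#' @param radius_scale tube radius per unit mean brightness (> 0).
#' @param tubes emit tessellated tube meshes instead of polylines.
#' @param tube_sides cross-section vertex count for tube meshes.
#' @param seed seed for the random segment colors.
#' @return Invisibly, a list with the obj, mtl and radius-table paths.
#' @export
export_obj <- function(model, path, radius_scale = 0.01, tubes = FALSE,
                       tube_sides = 8L, seed = 1L) {
  stopifnot_scalar(radius_scale, "radius_scale")
  stem <- sub("\\.obj$", "", path)
  mtl_path <- paste0(stem, ".mtl")
  radius_path <- paste0(stem, "_radii.csv")
  segs <- model$segments
  keep <- segs$arc_length > 0
  if (any(!keep))
    warning(sum(!keep), " zero-length segment(s) skipped")
  segs <- segs[keep, , drop = FALSE]
  radii <- data.frame(segment_id = segs$segment_id,
                      radius = radius_scale * segs$mean_intensity)
  write.csv(radii, radius_path, row.names = FALSE)

  set.seed(seed)
  cols <- t(vapply(seq_len(nrow(segs)),
                   function(k) grDevices::col2rgb(hsv(runif(1), 0.8, 0.9))[, 1L] / 255,
                   numeric(3)))
  mtl <- unlist(lapply(seq_len(nrow(segs)), function(k) c(
    sprintf("newmtl seg_%d", segs$segment_id[k]),
    sprintf("Kd %.4f %.4f %.4f", cols[k, 1L], cols[k, 2L], cols[k, 3L]))))
  writeLines(mtl, mtl_path)

  out <- c(sprintf("mtllib %s", basename(mtl_path)))
  offset <- 0L
  for (k in seq_len(nrow(segs))) {
    p <- as.matrix(segment_vertices(model, segs$segment_id[k])[, c("x", "y", "z")])
    out <- c(out, sprintf("usemtl seg_%d", segs$segment_id[k]))
    if (!tubes) {
      out <- c(out,
               sprintf("v %.6f %.6f %.6f", p[, 1L], p[, 2L], p[, 3L]),
               paste("l", paste(offset + seq_len(nrow(p)), collapse = " ")))
      offset <- offset + nrow(p)
    } else {
      fr <- transport_frames(p)
      r <- radii$radius[k]
      ang <- 2 * pi * (seq_len(tube_sides) - 1L) / tube_sides
      ring <- function(i) {
        ctr <- matrix(p[i, ], tube_sides, 3L, byrow = TRUE)
        ctr + r * (cos(ang) %o% fr$u[i, ] + sin(ang) %o% fr$v[i, ])
      }
      verts <- do.call(rbind, lapply(seq_len(nrow(p)), ring))
      out <- c(out, sprintf("v %.6f %.6f %.6f",
                            verts[, 1L], verts[, 2L], verts[, 3L]))
      for (i in seq_len(nrow(p) - 1L)) {
        a <- offset + (i - 1L) * tube_sides + seq_len(tube_sides)
        b <- offset + i * tube_sides + seq_len(tube_sides)
        a2 <- c(a[-1L], a[1L]); b2 <- c(b[-1L], b[1L])
        out <- c(out, sprintf("f %d %d %d %d", a, a2, b2, b))
      }
      offset <- offset + nrow(p) * tube_sides
    }
  }
  writeLines(out, path)
  invisible(list(obj = path, mtl = mtl_path, radii = radius_path))
}
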