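#' Fold-invariant chord orientation of a segment
#'
#' Segment start and end are interchangeable, so orientations differing by
#' 180 degrees are identical; the chord vector is flipped to the canonical
#' representative with azimuth in \[0, 180).  Azimuth is measured in the
#' xy-plane from +x, elevation from the horizontal plane (so a chord along
#' +z has elevation 90).
#'
#' @param segment polyline (data frame with x,y,z or n x 3 matrix) or a
#'   length-3 chord vector.
#' @return Named numeric `c(azimuth, elevation)` in degrees, or `NA`s for a
#'   zero chord.
#' @export
segment_orientation <- function(segment) {
  v <- if (is.numeric(segment) && length(segment) == 3L) segment else {
    p <- as_poly_matrix(segment)
    p[nrow(p), ] - p[1L, ]
  }
  if (all(v == 0)) return(c(azimuth = NA_real_, elevation = NA_real_))
  ## flip to azimuth in [0, 180): y > 0, or y == 0 with x > 0, or pure +-z
  if (v[2L] < 0 || (v[2L] == 0 && v[1L] < 0) ||
      (v[1L] == 0 && v[2L] == 0 && v[3L] < 0)) v <- -v
  v <- v + 0                                     # scrub IEEE negative zeros
  az <- rad2deg(atan2(v[2L], v[1L]))
  if (az < 0) az <- az + 180
  if (az >= 180) az <- az - 180
  el <- rad2deg(atan2(v[3L], sqrt(v[1L]^2 + v[2L]^2)))
  c(azimuth = az, elevation = el)
}

#' Deviation of a histogram from a reference distribution
#'
#' The deviation score is the sum over bins of the absolute difference
#' between the observed normalized frequency and the expected frequency:
#' 0 for a perfect match, at most `2 * (1 - 1/nbins)` (all mass in one bin).
#'
#' @param hist numeric vector of bin frequencies; normalized to sum 1 (a
#'   warning is issued and the input renormalized otherwise).
#' @param expected `"flat"` (each bin 1/nbins) or `"solid_angle"`
#'   (elevation histograms only: expected frequency proportional to the
#'   cosine of the bin-centre elevation, the density of an isotropic 3D
#'   orientation field).
#' @param bin_centers bin centres in degrees, required for
#'   `"solid_angle"`.
#' @return The deviation score (dimensionless).
#' @export
uniformity_deviation <- function(hist, expected = c("flat", "solid_angle"),
                                 bin_centers = NULL) {
  expected <- match.arg(expected)
  tot <- sum(hist)
  if (abs(tot - 1) > 1e-8) {
    warning("histogram not normalized; renormalizing")
    hist <- hist / tot
  }
  e <- if (expected == "flat") rep(1 / length(hist), length(hist)) else {
    if (is.null(bin_centers))
      stop("'bin_centers' required for solid_angle expectation", call. = FALSE)
    w <- cos(deg2rad(bin_centers))
    w / sum(w)
  }
  sum(abs(hist - e))
}

#' Cell centre: mean of the mean positions of all segments
#'
#' @param model a `filament_network`.
#' @return Length-3 numeric (x, y, z) in micrometres.
#' @export
cell_center <- function(model) {
  mids <- t(vapply(model$segments$segment_id, function(id) {
    colMeans(as.matrix(segment_vertices(model, id)[, c("x", "y", "z")]))
  }, numeric(3)))
  setNames(colMeans(mids), c("x", "y", "z"))
}

#' Outward-anchored chord vectors of all segments
#'
#' For each segment the endpoint closer to the cell centre is taken as the
#' origin, so every chord vector points outward from the centre.  Segments
#' whose endpoints are equidistant keep their stored orientation (the count
#' of such ties is attached as attribute `"n_ties"`).
#'
#' @param model a `filament_network`.
#' @param center cell centre; computed with [cell_center()] when missing.
#' @return n x 3 matrix of chord vectors, one row per segment, with the
#'   segment arc lengths as attribute `"arc_length"`.
#' @export
translocate_outward <- function(model, center = NULL) {
  if (is.null(center)) center <- cell_center(model)
  segs <- model$segments
  out <- matrix(0, nrow(segs), 3L)
  ties <- 0L
  for (k in seq_len(nrow(segs))) {
    p <- as.matrix(segment_vertices(model, segs$segment_id[k])[, c("x", "y", "z")])
    a <- p[1L, ]; b <- p[nrow(p), ]
    da <- sum((a - center)^2); db <- sum((b - center)^2)
    if (da == db) {
      ties <- ties + 1L
      out[k, ] <- b - a
    } else if (da < db) out[k, ] <- b - a else out[k, ] <- a - b
  }
  attr(out, "arc_length") <- segs$arc_length
  attr(out, "n_ties") <- ties
  out
}

#' Radial (rose) histograms of outward chord vectors
#'
#' Vectors are binned by the angle of their xy (respectively yz) projection
#' into `nbins` angular bins over \[0, 360); the bin weight is the summed
#' magnitude of the projected vectors, so longer chords contribute more —
#' the radii of the rose polygon.
#'
#' @param vectors n x 3 matrix of chord vectors (see
#'   [translocate_outward()]).
#' @param nbins number of angular bins (default 36, i.e. 10-degree bins).
#' @return List with numeric vectors `xy` and `yz` (bin weights, names =
#'   bin-centre angle in degrees).
#' @export
radial_histograms <- function(vectors, nbins = 36L) {
  bin_weights <- function(u, v) {
    mag <- sqrt(u^2 + v^2)
    keep <- mag > 0
    ang <- (rad2deg(atan2(v[keep], u[keep]))) %% 360
    b <- pmin(nbins, floor(ang / (360 / nbins)) + 1L)
    w <- numeric(nbins)
    for (i in seq_along(b)) w[b[i]] <- w[b[i]] + mag[keep][i]
    names(w) <- (seq_len(nbins) - 0.5) * (360 / nbins)
    w
  }
  list(xy = bin_weights(vectors[, 1L], vectors[, 2L]),
       yz = bin_weights(vectors[, 2L], vectors[, 3L]))
}

#' Network sum vector and anisotropy index
#'
#' Each segment contributes its outward unit chord direction weighted by its
#' arc length; the magnitude of the vector sum, normalized by the total arc
#' length, is the anisotropy index: 0 for a perfectly isotropic network, 1
#' for a fully parallel one.
#'
#' @param model a `filament_network`.
#' @param center optional precomputed cell centre.
#' @return List with `vector` (length-3, micrometres) and
#'   `anisotropy_index` in \[0, 1\].
#' @export
sum_vector <- function(model, center = NULL) {
  v <- translocate_outward(model, center)
  len <- attr(v, "arc_length")
  mag <- row_norms(v)
  keep <- mag > 0
  unit <- v[keep, , drop = FALSE] / mag[keep]
  sv <- colSums(unit * len[keep])
  list(vector = setNames(sv, c("x", "y", "z")),
       anisotropy_index = sqrt(sum(sv^2)) / sum(len[keep]))
}

#' Full orientation summary of a network
#'
#' Combines both directional analyses: (i) fold-invariant azimuth and
#' elevation histograms with uniformity deviation scores and (ii) the
#' centre-translocated radial histograms with the network sum vector.  The
#' elevation deviation is reported against both a flat reference (each
#' degree equally frequent) and the solid-angle-corrected reference, since
#' an isotropic 3D orientation field is not flat in elevation.
#'
#' @param model a `filament_network`.
#' @param azimuth_bins,elevation_bins histogram bin counts (default 180,
#'   i.e. 1-degree bins).
#' @param radial_bins angular bins for the rose histograms (default 36).
#' @return A list of class `orientation_summary`.
#' @export
orientation_summary <- function(model, azimuth_bins = 180L,
                                elevation_bins = 180L, radial_bins = 36L) {
  segs <- model$segments
  ornt <- t(vapply(segs$segment_id, function(id)
    segment_orientation(segment_vertices(model, id)), numeric(2)))
  ok <- stats::complete.cases(ornt)
  az <- ornt[ok, 1L]; el <- ornt[ok, 2L]
  az_counts <- tabulate(pmin(azimuth_bins,
                             floor(az / (180 / azimuth_bins)) + 1L),
                        nbins = azimuth_bins)
  el_bin <- pmin(elevation_bins,
                 floor((el + 90) / (180 / elevation_bins)) + 1L)
  el_counts <- tabulate(pmax(1L, el_bin), nbins = elevation_bins)
  az_hist <- az_counts / sum(az_counts)
  el_hist <- el_counts / sum(el_counts)
  az_centers <- (seq_len(azimuth_bins) - 0.5) * (180 / azimuth_bins)
  el_centers <- (seq_len(elevation_bins) - 0.5) * (180 / elevation_bins) - 90
  center <- cell_center(model)
  vecs <- translocate_outward(model, center)
  sv <- sum_vector(model, center)
  structure(list(
    azimuth_hist = setNames(az_hist, az_centers),
    elevation_hist = setNames(el_hist, el_centers),
    azimuth_deviation = uniformity_deviation(az_hist, "flat"),
    elevation_deviation = uniformity_deviation(el_hist, "flat"),
    elevation_deviation_solid_angle =
      uniformity_deviation(el_hist, "solid_angle", el_centers),
    radial = radial_histograms(vecs, radial_bins),
    sum_vector = sv$vector,
    anisotropy_index = sv$anisotropy_index,
    cell_center = center,
    n_segments = sum(ok)),
    class = "orientation_summary")
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat(sprintf("<orientation_summary> %d segments\n", x$n_segments))
  cat(sprintf("  azimuth deviation:   %.4f\n", x$azimuth_deviation))
  cat(sprintf("  elevation deviation: %.4f (flat), %.4f (solid angle)\n",
              x$elevation_deviation, x$elevation_deviation_solid_angle))
  cat(sprintf("  anisotropy index:    %.4f  sum vector (%.2f, %.2f, %.2f) um\n",
              x$anisotropy_index, x$sum_vector[1], x$sum_vector[2],
              x$sum_vector[3]))
  invisible(x)
}
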