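#' Curvature discretization parameters
#'
#' Curvature is measured as the magnitude of the derivative of the unit
#' tangent with respect to arc length after uniform resampling and
#' moving-average smoothing of the polyline.  The defaults are stable at
#' airyscan sampling (in-plane voxel about 0.044-0.065 um).
#'
#' @param resample_step uniform arc-length resampling step, micrometres.
#' @param smooth_window centred moving-average window (odd, >= 3 vertices).
#' @return A list of class `curvature_params`.
#' @export
curvature_params <- function(resample_step = 0.044, smooth_window = 5L) {
  stopifnot_scalar(resample_step, "resample_step")
  if (smooth_window < 3L || smooth_window %% 2L == 0L)
    stop("'smooth_window' must be an odd integer >= 3", call. = FALSE)
  structure(list(resample_step = resample_step,
                 smooth_window = as.integer(smooth_window)),
            class = "curvature_params")
}

as_poly_matrix <- function(segment) {
  if (is.data.frame(segment)) segment <- as.matrix(segment[, c("x", "y", "z")])
  if (!is.matrix(segment) || ncol(segment) != 3L)
    stop("segment must be a data frame with x,y,z or an n x 3 matrix",
         call. = FALSE)
  segment
}

#' Polyline arc length
#'
#' @param segment data frame with columns `x`, `y`, `z` (plus anything else)
#'   or an n x 3 coordinate matrix, vertex order = chain order.
#' @return Sum of consecutive Euclidean distances, micrometres.
#' @export
arc_length <- function(segment) {
  p <- as_poly_matrix(segment)
  if (nrow(p) < 2L) stop("segment needs >= 2 vertices", call. = FALSE)
  sum(row_norms(p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]))
}

#' Chord (end-to-end) length of a segment
#' @inheritParams arc_length
#' @export
chord_length <- function(segment) {
  p <- as_poly_matrix(segment)
  sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
}

#' Bending ratio: chord length over arc length
#'
#' 1 for a straight segment; approaches 0 for a closed loop (coincident
#' endpoints with nonzero arc give exactly 0).
#'
#' @inheritParams arc_length
#' @return Value in (0, 1\] (0 for a loop).
#' @export
bending_ratio <- function(segment) {
  a <- arc_length(segment)
  if (a <= 0) stop("zero arc length", call. = FALSE)
  chord_length(segment) / a
}

#' Resample a polyline at uniform arc-length spacing
#'
#' Linear interpolation along the chain; first and last points are kept.
#'
#' @param p n x 3 coordinate matrix.
#' @param step target spacing, micrometres.
#' @return m x 3 matrix, m >= 2.
#' @keywords internal
resample_polyline <- function(p, step) {
  seglen <- row_norms(p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  m <- max(2L, as.integer(round(total / step)) + 1L)
  si <- seq(0, total, length.out = m)
  out <- matrix(0, m, 3L)
  for (d in 1:3) out[, d] <- stats::approx(s, p[, d], xout = si, ties = "ordered")$y
  out
}

moving_average <- function(m, w) {
  ## centred moving average per column, dropping the edge rows that lack a
  ## full window
  k <- (w - 1L) %/% 2L
  n <- nrow(m)
  if (n < w) return(m[integer(0), , drop = FALSE])
  out <- matrix(0, n - 2L * k, ncol(m))
  for (d in seq_len(ncol(m))) {
    cs <- cumsum(c(0, m[, d]))
    out[, d] <- (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w
  }
  out
}

#' Mean unsigned curvature of a segment
#'
#' The polyline is resampled at uniform arc step, smoothed by a centred
#' moving average, unit tangents are taken by central differences and the
#' curvature at each interior sample is the magnitude of the tangent
#' derivative with respect to arc length.  Returns `NA` (with the reason
#' recorded) when the segment is too short to support the stencil.
#'
#' @inheritParams arc_length
#' @param params a [curvature_params].
#' @return Mean curvature in 1/micrometres, or `NA` for too-short segments.
#' @export
mean_curvature <- function(segment, params = curvature_params()) {
  p <- as_poly_matrix(segment)
  h <- params$resample_step
  r <- resample_polyline(p, h)
  r <- moving_average(r, params$smooth_window)
  if (nrow(r) < 4L) return(NA_real_)
  ## recompute the actual uniform step after smoothing (smoothing preserves
  ## spacing to first order; use mean consecutive distance)
  tang <- r[-1L, , drop = FALSE] - r[-nrow(r), , drop = FALSE]
  hs <- mean(row_norms(tang))
  tn <- (r[3:nrow(r), , drop = FALSE] - r[1:(nrow(r) - 2L), , drop = FALSE])
  tn <- tn / row_norms(tn)                      # unit tangent, central diff
  if (nrow(tn) < 3L) return(NA_real_)
  dT <- tn[3:nrow(tn), , drop = FALSE] - tn[1:(nrow(tn) - 2L), , drop = FALSE]
  mean(row_norms(dT) / (2 * hs))
}

#' Per-segment metric table
#'
#' One row per segment with arc length, chord length, bending ratio, mean
#' brightness, mean curvature and the fold-invariant chord orientation
#' (azimuth in \[0, 180), elevation in (-90, 90\], degrees).  Segments too
#' short for the curvature stencil get `NA` curvature; their count is
#' reported as attribute `"n_curvature_excluded"`.
#'
#' @param model a `filament_network`.
#' @param params a [curvature_params].
#' @param length_weighted if `TRUE`, segment brightness is the arc-length
#'   weighted mean of vertex intensities instead of the plain mean.
#' @return Data frame of class `segment_metrics`.
#' @export
segment_metrics <- function(model, params = curvature_params(),
                            length_weighted = FALSE) {
  segs <- model$segments
  out <- data.frame(segment_id = segs$segment_id,
                    arc_length = NA_real_, chord_length = NA_real_,
                    bending_ratio = NA_real_, mean_brightness = NA_real_,
                    mean_curvature = NA_real_,
                    azimuth = NA_real_, elevation = NA_real_)
  for (k in seq_len(nrow(segs))) {
    v <- segment_vertices(model, segs$segment_id[k])
    p <- as.matrix(v[, c("x", "y", "z")])
    out$arc_length[k] <- arc_length(p)
    out$chord_length[k] <- chord_length(p)
    out$bending_ratio[k] <- out$chord_length[k] / out$arc_length[k]
    out$mean_brightness[k] <- if (length_weighted) {
      mids <- (v$intensity[-1L] + v$intensity[-nrow(v)]) / 2
      w <- row_norms(p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])
      sum(mids * w) / sum(w)
    } else mean(v$intensity)
    out$mean_curvature[k] <- mean_curvature(p, params)
    ornt <- segment_orientation(p)
    out$azimuth[k] <- ornt[1L]
    out$elevation[k] <- ornt[2L]
  }
  attr(out, "n_curvature_excluded") <- sum(is.na(out$mean_curvature))
  class(out) <- c("segment_metrics", "data.frame")
  out
}

#' Pearson correlation between segment thickness and curvature
#'
#' Brightness is the proxy for filament-bundle thickness; a near-zero
#' correlation indicates that bundling and bending are unrelated.
#'
#' @param metrics a [segment_metrics] table.
#' @return Pearson r.
#' @export
thickness_curvature_correlation <- function(metrics) {
  ok <- stats::complete.cases(metrics[, c("mean_brightness", "mean_curvature")])
  if (sum(ok) < 3L)
    stop("need >= 3 segments with brightness and curvature", call. = FALSE)
  cor(metrics$mean_brightness[ok], metrics$mean_curvature[ok])
}

#' Cell volume from an image stack by intensity thresholding
#'
#' Counts voxels at or above a threshold that separates intracellular from
#' extracellular background fluorescence and multiplies by the voxel volume.
#'
#' @param stack an [image_stack].
#' @param method `"fixed"` uses `level` as the threshold; `"otsu"` derives it
#'   from the pooled voxel histogram (requires the EBImage package).
#' @param level threshold intensity for `method = "fixed"`.
#' @return Volume in cubic micrometres.
#' @export
cell_volume <- function(stack, method = c("fixed", "otsu"), level = 0) {
  method <- match.arg(method)
  vox <- stack$voxels
  mx <- max(vox)
  if (mx == 0) {
    warning("all-zero stack; volume 0")
    return(0)
  }
  thr <- if (method == "fixed") level else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("method 'otsu' requires the EBImage package", call. = FALSE)
    ## Otsu only uses the intensity histogram, so the stack is passed as one
    ## flattened grayscale frame
    flat <- EBImage::Image(matrix(vox / mx, nrow = dim(vox)[1L]))
    EBImage::otsu(flat, range = c(0, 1), levels = 256L) * mx
  }
  sum(vox >= thr) * prod(stack$spacing)
}

#' Per-cell summary metrics
#'
#' Aggregates a network model into the per-cell quantities: segment count,
#' mean and total segment length (total also in mm), filament density
#' (length per volume, when a cell volume is supplied), apparent persistence
#' length, the brightness histogram with the maximum segment brightness
#' normalized to 100, and the thickness-curvature Pearson correlation.
#'
#' @param model a `filament_network`.
#' @param volume cell volume in cubic micrometres, or `NA` when unknown.
#' @param params a [curvature_params].
#' @param max_lag maximum contour lag for the persistence-length fit,
#'   micrometres.
#' @param nbins number of brightness histogram bins over \[0, 100\].
#' @return A list of class `cell_metrics`.
#' @export
cell_totals <- function(model, volume = NA_real_,
                        params = curvature_params(), max_lag = 2,
                        nbins = 50L) {
  if (!nrow(model$segments)) stop("empty network model", call. = FALSE)
  sm <- segment_metrics(model, params)
  total <- sum(sm$arc_length)
  bright <- sm$mean_brightness
  scaled <- if (max(bright) > 0) bright / max(bright) * 100 else bright
  breaks <- seq(0, 100, length.out = nbins + 1L)
  counts <- tabulate(pmin(nbins, findInterval(scaled, breaks,
                                              rightmost.closed = TRUE)),
                     nbins = nbins)
  hist_df <- data.frame(brightness = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                        frequency = counts / sum(counts))
  lp <- apparent_persistence_length(model, max_lag = max_lag)
  ## degenerate inputs (too few segments, zero variance) give NA, not a fit
  pear <- tryCatch(suppressWarnings(thickness_curvature_correlation(sm)),
                   error = function(e) NA_real_)
  if (is.nan(pear)) pear <- NA_real_
  structure(list(
    cell_id = model$cell_id,
    n_segments = nrow(sm),
    mean_segment_length = mean(sm$arc_length),
    total_length_um = total,
    total_length_mm = total / 1000,
    cell_volume = volume,
    density = if (is.na(volume)) NA_real_ else total / volume,
    apparent_persistence_length = lp$Lp,
    brightness_histogram = hist_df,
    thickness_curvature_pearson = pear,
    n_curvature_excluded = attr(sm, "n_curvature_excluded")),
    class = "cell_metrics")
}

#' @export
print.cell_metrics <- function(x, ...) {
  cat(sprintf("<cell_metrics> '%s'\n", x$cell_id))
  cat(sprintf("  segments: %d, mean length %.3f um, total %.4f mm\n",
              x$n_segments, x$mean_segment_length, x$total_length_mm))
  if (!is.na(x$density))
    cat(sprintf("  density: %.2f um/um^3 (volume %.2f um^3)\n",
                x$density, x$cell_volume))
  cat(sprintf("  apparent persistence length: %.3g um\n",
              x$apparent_persistence_length))
  cat(sprintf("  thickness-curvature Pearson r: %.3f\n",
              x$thickness_curvature_pearson))
  invisible(x)
}
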