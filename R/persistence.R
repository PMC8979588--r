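#' Apparent persistence length from pooled tangent correlations
#'
#' Tangent-tangent correlations `<cos theta(ds)>` are pooled over all
#' segments at binned contour lags up to `max_lag`, and the 3D worm-like
#' chain decay `<cos theta> = exp(-ds / Lp)` is fitted by through-origin
#' least squares on `ln <cos theta>`.  The result is "apparent" because
#' network-embedded segments are constrained at nodes rather than free.
#'
#' Segments are resampled at a uniform step before tangents are taken.  When
#' a mean correlation in the fit range is non-positive the fit is restricted
#' to the positive prefix of lags (with a warning); perfectly straight input
#' has no decay and returns `Inf`.
#'
#' @param segments a `filament_network`, or a list of polylines (data frames
#'   with x,y,z or n x 3 matrices).
#' @param max_lag maximum contour lag, micrometres.
#' @param step resampling / lag bin step, micrometres.
#' @return List with `Lp` (micrometres), the lag table `correlations`
#'   (data frame lag, mean_cos, n_pairs) and `convention = "3d"`.
#' @export
apparent_persistence_length <- function(segments, max_lag = 2, step = 0.05) {
  stopifnot_scalar(max_lag, "max_lag")
  stopifnot_scalar(step, "step")
  if (inherits(segments, "filament_network")) {
    model <- segments
    segments <- lapply(model$segments$segment_id,
                       function(id) segment_vertices(model, id))
  }
  nlag <- max(1L, as.integer(floor(max_lag / step)))
  sum_cos <- numeric(nlag)
  n_pairs <- numeric(nlag)
  for (seg in segments) {
    p <- as_poly_matrix(seg)
    if (nrow(p) < 2L) next
    r <- resample_polyline(p, step)
    tn <- r[-1L, , drop = FALSE] - r[-nrow(r), , drop = FALSE]
    nt <- nrow(tn)
    if (nt < 2L) next
    tn <- tn / row_norms(tn)
    for (k in seq_len(min(nlag, nt - 1L))) {
      dots <- rowSums(tn[1:(nt - k), , drop = FALSE] *
                      tn[(1L + k):nt, , drop = FALSE])
      sum_cos[k] <- sum_cos[k] + sum(dots)
      n_pairs[k] <- n_pairs[k] + length(dots)
    }
  }
  have <- n_pairs > 0
  lag <- seq_len(nlag) * step
  corr <- data.frame(lag = lag[have],
                     mean_cos = sum_cos[have] / n_pairs[have],
                     n_pairs = n_pairs[have])
  if (!nrow(corr)) stop("no tangent pairs within max_lag", call. = FALSE)
  usable <- corr$mean_cos > 0
  if (!all(usable)) {
    warning("non-positive tangent correlations in fit range; ",
            "fitting positive prefix only")
    first_bad <- which(!usable)[1L]
    corr_fit <- corr[seq_len(first_bad - 1L), , drop = FALSE]
  } else corr_fit <- corr
  if (!nrow(corr_fit)) stop("no positive correlations to fit", call. = FALSE)
  y <- log(corr_fit$mean_cos)
  s <- corr_fit$lag
  slope <- sum(s * y) / sum(s * s)              # through-origin LS
  Lp <- if (slope >= 0) Inf else -1 / slope
  list(Lp = Lp, correlations = corr, convention = "3d")
}
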