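#' Published per-cell reference measurements for the three cell types
#'
#' Mean and standard deviation of the per-cell network metrics reported for
#' single MDCK, HaCaT and RPE cells (ten cells per type, airyscan
#' recordings).  These values are not desk-reproducible from synthetic
#' data; they serve as regression bands for pipelines re-run on the
#' archived single-cell deposit (see the package README for the accession).
#'
#' @return Data frame with columns `cell_type`, `metric`, `mean`, `sd`,
#'   `units`.
#' @export
reference_measurements <- function() {
  rbind(
    data.frame(cell_type = "MDCK",
               metric = c("mean_segment_length", "total_length_mm",
                          "cell_volume", "density", "bending_ratio",
                          "mean_curvature", "thickness_curvature_pearson",
                          "apparent_persistence_length",
                          "mass_mpl_pg", "mass_tetramer_pg"),
               mean = c(0.80, 1.63, 4.65, 355.24, 0.92, 2.54, -0.10, 2.6, 1.3, 1.4),
               sd = c(0.04, 0.41, 1.13, 56.49, 0.09, 0.11, NA, NA, NA, NA)),
    data.frame(cell_type = "HaCaT",
               metric = c("mean_segment_length", "total_length_mm",
                          "cell_volume", "density", "bending_ratio",
                          "mean_curvature", "thickness_curvature_pearson",
                          "apparent_persistence_length",
                          "mass_mpl_pg", "mass_tetramer_pg"),
               mean = c(0.83, 4.40, 9.16, 604.82, 0.92, 2.97, 0.08, 2.6, 3.47, 4.3),
               sd = c(0.13, 1.53, 6.10, 304.20, 0.08, 0.72, NA, NA, NA, NA)),
    data.frame(cell_type = "RPE",
               metric = c("mean_segment_length", "total_length_mm",
                          "cell_volume", "density", "bending_ratio",
                          "mean_curvature", "thickness_curvature_pearson",
                          "apparent_persistence_length",
                          "mass_mpl_pg", "mass_tetramer_pg"),
               mean = c(0.88, 1.57, 2.73, 585.60, 0.90, 3.30, 0.14, 2.6, 1.2, 1.4),
               sd = c(0.05, 0.48, 0.95, 63.97, 0.10, 0.15, NA, NA, NA, NA)),
    make.row.names = FALSE)
}

#' Compare computed cell metrics against the published reference bands
#'
#' A regression gate for re-runs on the archived single-cell data: each
#' computed metric is checked against the published mean plus/minus one
#' standard deviation.  Metrics without a published SD are compared at 15
#' percent relative tolerance.
#'
#' @param metrics a [cell_totals()] result (or a named list holding a
#'   subset of its fields).
#' @param cell_type `"MDCK"`, `"HaCaT"` or `"RPE"`.
#' @return Data frame with columns `metric`, `value`, `mean`, `sd`,
#'   `within_band`.
#' @export
regression_against_reference <- function(metrics, cell_type) {
  ref <- reference_measurements()
  ref <- ref[ref$cell_type == cell_type, ]
  if (!nrow(ref)) stop("unknown cell type: ", cell_type, call. = FALSE)
  value_of <- function(metric) {
    v <- switch(
      metric,
      mean_segment_length = metrics$mean_segment_length,
      total_length_mm = metrics$total_length_mm,
      cell_volume = metrics$cell_volume,
      density = metrics$density,
      bending_ratio = metrics$mean_bending_ratio,
      mean_curvature = metrics$mean_curvature,
      thickness_curvature_pearson = metrics$thickness_curvature_pearson,
      apparent_persistence_length = metrics$apparent_persistence_length,
      mass_mpl_pg = if (is.null(metrics$total_length_mm)) NULL
                    else mass_mpl(metrics$total_length_mm),
      mass_tetramer_pg = if (is.null(metrics$total_length_mm)) NULL
                         else mass_tetramer(metrics$total_length_mm)$mass_pg,
      NULL)
    v %||% NA_real_
  }
  out <- ref[c("metric", "mean", "sd")]
  out$value <- vapply(out$metric, value_of, numeric(1))
  out$within_band <- ifelse(
    is.na(out$value), NA,
    ifelse(is.na(out$sd),
           abs(out$value - out$mean) <= 0.15 * abs(out$mean),
           abs(out$value - out$mean) <= out$sd))
  out[c("metric", "value", "mean", "sd", "within_band")]
}
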