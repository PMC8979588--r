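utils::globalVariables(c("x", "y", "value"))

#' Heat-map of a segment property at vertex locations
#'
#' Plots every vertex of the network color-coded by a segment property —
#' the spatial map form used to inspect where thick, long or strongly bent
#' filaments sit in the cell.
#'
#' @param model a `filament_network`.
#' @param property `"brightness"`, `"length"`, `"curvature"` or
#'   `"azimuth"`.
#' @param projection `"xy"` plots all vertices (maximum-projection view);
#'   `"slice"` restricts to vertices within half a voxel of `slice_z`.
#' @param slice_z z position of the slice, micrometres.
#' @param slice_halfwidth half thickness of the slice, micrometres.
#' @param params [curvature_params] used when `property = "curvature"`.
#' @return A ggplot object.
#' @export
property_heatmap <- function(model,
                             property = c("brightness", "length",
                                          "curvature", "azimuth"),
                             projection = c("xy", "slice"),
                             slice_z = NULL, slice_halfwidth = 0.1,
                             params = curvature_params()) {
  property <- match.arg(property)
  projection <- match.arg(projection)
  per_segment <- switch(
    property,
    brightness = model$segments$mean_intensity,
    length = model$segments$arc_length,
    curvature = vapply(model$segments$segment_id, function(id)
      mean_curvature(segment_vertices(model, id), params), numeric(1)),
    azimuth = vapply(model$segments$segment_id, function(id)
      segment_orientation(segment_vertices(model, id))[1L], numeric(1)))
  if (all(is.na(per_segment)))
    stop("property '", property, "' has no finite values", call. = FALSE)
  df <- model$vertices
  df$value <- per_segment[match(df$segment_id, model$segments$segment_id)]
  if (projection == "slice") {
    if (is.null(slice_z)) stop("'slice_z' required for slice projection",
                               call. = FALSE)
    df <- df[abs(df$z - slice_z) <= slice_halfwidth, , drop = FALSE]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = value)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_viridis_c(name = property) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("%s map, cell '%s'", property,
                                  model$cell_id)) +
    ggplot2::theme_minimal()
}
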