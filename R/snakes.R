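#' Snake sets: polygonal-chain segmentations with per-vertex brightness
#'
#' A snake is an ordered 3D polygonal chain of vertices produced by an
#' open-active-contour segmentation of a filament; every vertex carries an
#' xyz position (micrometres) and a fluorescence intensity (arbitrary
#' units).  A `snake_set` stores all snakes of one cell as a single
#' data frame with columns `snake_id`, `x`, `y`, `z`, `intensity`; row order
#' within a snake is the vertex order.
#'
#' @param vertices data frame with columns `snake_id`, `x`, `y`, `z`,
#'   `intensity`.  Rows of one snake must be contiguous.
#' @return An object of class `snake_set` (a data frame).
#' @examples
#' s <- snake_set(data.frame(snake_id = 1, x = 0:2, y = 0, z = 0,
#'                           intensity = 10))
#' n_snakes(s)
#' @export
snake_set <- function(vertices) {
  required <- c("snake_id", "x", "y", "z", "intensity")
  missing_cols <- setdiff(required, names(vertices))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  vertices <- as.data.frame(vertices)[required]
  for (col in required) {
    if (!is.numeric(vertices[[col]]))
      stop("column '", col, "' must be numeric", call. = FALSE)
  }
  if (nrow(vertices)) {
    if (!all(is.finite(as.matrix(vertices[c("x", "y", "z")]))))
      stop("vertex positions must be finite", call. = FALSE)
    if (any(vertices$intensity < 0))
      stop("vertex intensities must be >= 0", call. = FALSE)
    ids <- vertices$snake_id
    runs <- rle(ids)
    if (anyDuplicated(runs$values))
      stop("snakes must be contiguous: snake_id ",
           runs$values[anyDuplicated(runs$values)],
           " appears in more than one block", call. = FALSE)
    if (any(runs$lengths < 2L))
      stop("snake ", runs$values[which(runs$lengths < 2L)[1L]],
           " has fewer than 2 vertices", call. = FALSE)
    ## consecutive vertices of one snake must be distinct points
    p <- as.matrix(vertices[c("x", "y", "z")])
    same_snake <- ids[-1L] == ids[-length(ids)]
    step <- row_norms(p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])
    if (any(same_snake & step == 0))
      stop("snake ", ids[which(same_snake & step == 0)[1L]],
           " contains coincident consecutive vertices", call. = FALSE)
  }
  class(vertices) <- c("snake_set", "data.frame")
  vertices
}

#' @rdname snake_set
#' @param x a `snake_set`.
#' @export
n_snakes <- function(x) length(unique(x$snake_id))

#' Split a snake set into one matrix of vertex rows per snake
#'
#' @param x a `snake_set`.
#' @return Named list (by snake id) of data frames with columns
#'   `x`, `y`, `z`, `intensity`, in vertex order.
#' @keywords internal
snake_list <- function(x) {
  split(as.data.frame(x)[c("x", "y", "z", "intensity")],
        factor(x$snake_id, levels = unique(x$snake_id)))
}

#' @export
print.snake_set <- function(x, ...) {
  cat(sprintf("<snake_set> %d snakes, %d vertices\n", n_snakes(x), nrow(x)))
  if (nrow(x)) {
    lens <- rle(x$snake_id)$lengths
    cat(sprintf("  vertices per snake: median %g (range %d-%d)\n",
                stats::median(lens), min(lens), max(lens)))
  }
  invisible(x)
}

#' In-memory 3D image stack with anisotropic voxel spacing
#'
#' @param voxels numeric 3D array of non-negative intensities, indexed
#'   (z, y, x).  A matrix is promoted to a single z-plane.
#' @param spacing numeric length-3 vector of voxel edge lengths in
#'   micrometres, ordered (z, y, x).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing) {
  if (is.matrix(voxels)) dim(voxels) <- c(1L, dim(voxels))
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !length(voxels))
    stop("'voxels' must be a non-empty 3D array (z, y, x)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers (z, y, x) in um", call. = FALSE)
  structure(list(voxels = voxels, spacing = setNames(spacing, c("z", "y", "x"))),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d (z,y,x), voxel %g x %g x %g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}
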