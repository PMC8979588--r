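#' Read snake files
#'
#' Reads a snake segmentation from disk into a [snake_set].  Two dialects are
#' supported:
#'
#' * `"tsoax"` — the text layout written by SOAC-family segmenters: header
#'   lines starting with `#` or `$` (ignored), then whitespace-separated rows
#'   `snake_id point_index x y z intensity`.  Rows of one snake must be
#'   contiguous with ascending `point_index`.  An optional trailing junction
#'   section introduced by a line starting with `[` is parsed and attached as
#'   attribute `"junctions"` but otherwise ignored: node association is
#'   recomputed by [build_network()].
#' * `"polyline_table"` — a delimited table (comma, tab or whitespace) with
#'   header columns `snake_id`, `x`, `y`, `z`, `intensity`.
#'
#' @param path path to an existing file.
#' @param dialect `"tsoax"` or `"polyline_table"`.
#' @param scale factor applied to the raw coordinates to convert them to
#'   micrometres (use the voxel size for files written in voxel units).
#' @return A [snake_set] with coordinates in micrometres.
#' @export
read_snakes <- function(path, dialect = c("tsoax", "polyline_table"),
                        scale = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot_scalar(scale, "scale")
  if (dialect == "tsoax") {
    lines <- readLines(path)
    junction_start <- grep("^\\s*\\[", lines)[1L]
    junctions <- character(0)
    if (!is.na(junction_start)) {
      junctions <- lines[junction_start:length(lines)]
      lines <- lines[seq_len(junction_start - 1L)]
      message(length(junctions), " junction line(s) parsed and ignored; ",
              "nodes are recomputed from vertex proximity")
    }
    keep <- !grepl("^\\s*(#|\\$)", lines) & nzchar(trimws(lines))
    data_lineno <- which(keep)
    rows <- strsplit(trimws(lines[keep]), "\\s+")
    if (!length(rows)) {
      s <- snake_set(data.frame(snake_id = numeric(0), x = numeric(0),
                                y = numeric(0), z = numeric(0),
                                intensity = numeric(0)))
      if (length(junctions)) attr(s, "junctions") <- junctions
      return(s)
    }
    nfield <- lengths(rows)
    if (any(nfield != 6L))
      stop("line ", data_lineno[which(nfield != 6L)[1L]],
           ": expected 6 fields (snake_id point_index x y z intensity)",
           call. = FALSE)
    m <- suppressWarnings(
      matrix(as.numeric(unlist(rows)), ncol = 6L, byrow = TRUE))
    if (anyNA(m))
      stop("line ", data_lineno[which(rowSums(is.na(m)) > 0)[1L]],
           ": non-numeric field", call. = FALSE)
    ## point_index must ascend within each snake
    ids <- m[, 1L]
    same <- ids[-1L] == ids[-length(ids)]
    if (any(same & diff(m[, 2L]) <= 0))
      stop("line ", data_lineno[which(same & diff(m[, 2L]) <= 0)[1L] + 1L],
           ": point_index must be ascending within a snake", call. = FALSE)
    df <- data.frame(snake_id = m[, 1L], x = m[, 3L] * scale,
                     y = m[, 4L] * scale, z = m[, 5L] * scale,
                     intensity = m[, 6L])
  } else {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(",", header)) "," else ""
    df <- read.table(path, header = TRUE, sep = sep,
                     comment.char = "#", strip.white = TRUE)
    required <- c("snake_id", "x", "y", "z", "intensity")
    if (length(setdiff(required, names(df))))
      stop("polyline table misses column(s): ",
           paste(setdiff(required, names(df)), collapse = ", "),
           call. = FALSE)
    for (col in required)
      if (!is.numeric(df[[col]]))
        stop("column '", col, "' is not numeric", call. = FALSE)
    df$x <- df$x * scale; df$y <- df$y * scale; df$z <- df$z * scale
  }
  s <- snake_set(df)
  if (dialect == "tsoax" && length(junctions))
    attr(s, "junctions") <- junctions
  s
}

#' Write snake files
#'
#' Inverse of [read_snakes()]; refuses to write non-finite coordinates.
#'
#' @param snakes a [snake_set] (may be empty: a header-only file is written).
#' @inheritParams read_snakes
#' @return `path`, invisibly.
#' @export
write_snakes <- function(snakes, path, dialect = c("tsoax", "polyline_table")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(snakes)
  if (nrow(df) && !all(is.finite(as.matrix(df[c("x", "y", "z", "intensity")]))))
    stop("refusing to write non-finite vertex data", call. = FALSE)
  if (dialect == "tsoax") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# snake_id point_index x y z intensity", con)
    if (nrow(df)) {
      point_index <- unlist(lapply(rle(df$snake_id)$lengths, seq_len),
                            use.names = FALSE)
      writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g",
                         as.integer(df$snake_id), point_index,
                         df$x, df$y, df$z, df$intensity), con)
    }
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into an [image_stack], page
#' order taken as z order.  Voxel spacing is resolved in this order: the
#' `spacing` argument; a `<path>.meta.json` sidecar (written by
#' [write_stack()]); TIFF metadata (x/y resolution tags plus an
#' ImageJ-style `spacing=` entry in the image description, as written by
#' Fiji).  With none of the three the read fails.  RGB input is rejected.
#'
#' @param path path to a TIFF file.
#' @param spacing optional length-3 numeric (z, y, x) voxel size in
#'   micrometres overriding all file metadata.
#' @return An [image_stack].
#' @export
read_stack <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("multi-channel (RGB) TIFF not supported; convert to grayscale",
         call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  if (is.null(spacing)) {
    if (!is.null(meta)) {
      spacing <- as.numeric(unlist(meta$spacing_zyx_um))
    } else {
      info <- attributes(pages[[1L]])
      zsp <- sub_number(info$description %||% "", "spacing=")
      xres <- info$x.resolution
      if (is.na(zsp) || is.null(xres) || !is.finite(xres) || xres <= 0)
        stop("no voxel spacing in TIFF metadata; pass 'spacing = c(z, y, x)'",
             call. = FALSE)
      yres <- info$y.resolution %||% xres
      spacing <- c(zsp, 1 / yres, 1 / xres)
    }
  }
  vox <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (k in seq_along(pages)) vox[k, , ] <- pages[[k]]
  if (!is.null(meta) && !is.null(meta$max_intensity) && max(vox) > 0)
    vox <- vox * (as.numeric(meta$max_intensity) / max(vox))
  image_stack(vox, spacing)
}

sub_number <- function(text, key) {
  m <- regmatches(text, regexpr(paste0(key, "[0-9.eE+-]+"), text))
  if (!length(m)) return(NA_real_)
  as.numeric(sub(key, "", m))
}

#' Write an [image_stack] as a multi-page 32-bit float TIFF
#'
#' Intensities are stored normalized to \[0, 1\] (the float TIFF range the
#' writer supports); the original maximum and the voxel spacing are recorded
#' in a `<path>.meta.json` sidecar from which [read_stack()] restores them.
#'
#' @param stack an [image_stack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  vox <- stack$voxels
  mx <- max(vox)
  norm <- if (mx > 0) vox / mx else vox
  d <- dim(vox)
  pages <- lapply(seq_len(d[1L]), function(k) norm[k, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(
    list(spacing_zyx_um = as.numeric(stack$spacing), max_intensity = mx,
         unit = "micron"),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
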