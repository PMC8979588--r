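#' Default configuration
#'
#' A flat, typed key-value configuration with explicit units in the key
#' names, guarding against the nm/um/mm unit pitfalls of this analysis.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    epsilon_um = NA_real_,          # NA: derive from reference voxel
    reference_voxel_um = 0.065,
    voxel_z_um = 0.18,
    voxel_y_um = 0.065,
    voxel_x_um = 0.065,
    coordinate_scale = 1,           # raw snake units -> um
    resample_step_um = 0.044,
    smooth_window = 5L,
    max_lag_um = 2,
    brightness_bins = 50L,
    diameter_scale = 0.05,          # render: disc px per intensity unit
    blur_sigma_x_px = 5, blur_sigma_y_px = 5, blur_sigma_z_px = 3,
    radius_scale = 0.01,            # obj: tube radius per intensity unit
    seed = 1L)
}

#' Read a YAML configuration file
#'
#' Unknown keys trigger a warning and are ignored; known keys must have the
#' type of their default.
#'
#' @param path YAML file with flat keys as in [default_config()].
#' @return Named list: the defaults overridden by the file.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in intersect(names(user), names(cfg))) {
    val <- user[[key]]
    if (!is.numeric(val) || length(val) != 1L)
      stop("config key '", key, "' must be a single number", call. = FALSE)
    cfg[[key]] <- if (is.integer(cfg[[key]])) as.integer(val) else as.numeric(val)
  }
  cfg
}

config_epsilon <- function(cfg) {
  if (is.na(cfg$epsilon_um)) 1.1 * cfg$reference_voxel_um else cfg$epsilon_um
}
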