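#' Parameters of the synthetic network / image generator
#'
#' Defaults emulate the imaging conditions of the source recordings:
#' anisotropic voxels of 0.065 um in plane and 0.18 um along the optical
#' axis, filament persistence length 2.6 um, and a flat epithelial-cell
#' sized box.  `junction_jitter` must stay below half the clustering
#' epsilon so that planted junctions are always recovered as single nodes.
#'
#' @param box simulation box (x, y, z), micrometres.
#' @param n_filaments number of primary filaments.
#' @param filament_length contour length per filament, micrometres.
#' @param step polyline step, micrometres.
#' @param persistence_length worm-like-chain persistence length, micrometres.
#' @param branch_probability per-filament probability of carrying one
#'   planted Y-junction.
#' @param brightness_meanlog,brightness_sdlog log-normal brightness
#'   distribution of segments, arbitrary units.
#' @param junction_jitter maximal offset of a planted branch origin from its
#'   parent vertex, micrometres.
#' @param voxel_spacing voxel size (z, y, x), micrometres.
#' @param psf_sigma Gaussian point-spread sigmas (x, y, z), micrometres.
#' @param noise_sd additive Gaussian noise sigma, arbitrary units.
#' @param poisson_noise if `TRUE`, shot noise is applied to the signal.
#' @param min_separation if > 0, filaments are resampled until they keep at
#'   least this distance from previously placed ones (junction
#'   neighbourhoods excepted), guaranteeing that only planted junctions
#'   cluster.
#' @param seed RNG seed; same seed, same output, byte for byte.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(box = c(15, 15, 4), n_filaments = 30,
                         filament_length = 5, step = 0.1,
                         persistence_length = 2.6,
                         branch_probability = 0.3,
                         brightness_meanlog = log(50),
                         brightness_sdlog = 0.5,
                         junction_jitter = 0.02,
                         voxel_spacing = c(0.18, 0.065, 0.065),
                         psf_sigma = c(0.13, 0.13, 0.3),
                         noise_sd = 2, poisson_noise = FALSE,
                         min_separation = 0, seed = 1L) {
  p <- list(box = box, n_filaments = n_filaments,
            filament_length = filament_length, step = step,
            persistence_length = persistence_length,
            branch_probability = branch_probability,
            brightness_meanlog = brightness_meanlog,
            brightness_sdlog = brightness_sdlog,
            junction_jitter = junction_jitter,
            voxel_spacing = voxel_spacing, psf_sigma = psf_sigma,
            noise_sd = noise_sd, poisson_noise = poisson_noise,
            min_separation = min_separation, seed = as.integer(seed))
  for (nm in c("filament_length", "step", "persistence_length"))
    stopifnot_scalar(p[[nm]], nm)
  if (any(box <= 0)) stop("box dimensions must be positive", call. = FALSE)
  if (p$step >= min(box))
    stop("box too small for the polyline step", call. = FALSE)
  structure(p, class = "synth_params")
}

#' Discrete worm-like chain
#'
#' Standard discretization: starting from a random (or given) unit tangent,
#' each step perturbs the tangent by two transverse Gaussian components of
#' variance `step / Lp` each, so that the tangent correlation decays as
#' `exp(-ds / Lp)` (3D convention).  The chain is reflected at the walls of
#' `box` when given.
#'
#' @param n_steps number of steps (chain has `n_steps + 1` vertices).
#' @param step step length, micrometres.
#' @param Lp persistence length, micrometres.
#' @param start length-3 start position.
#' @param t0 optional initial unit tangent.
#' @param box optional (x, y, z) box for reflecting boundaries.
#' @return (n_steps + 1) x 3 coordinate matrix.
#' @export
wlc_chain <- function(n_steps, step, Lp, start = c(0, 0, 0), t0 = NULL,
                      box = NULL) {
  p <- matrix(0, n_steps + 1L, 3L)
  p[1L, ] <- start
  t <- if (is.null(t0)) random_unit_vectors(1L)[1L, ] else t0 / sqrt(sum(t0^2))
  sdv <- sqrt(step / Lp)
  for (i in seq_len(n_steps)) {
    ## orthonormal frame transverse to t
    ref <- if (abs(t[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * t) * t
    u <- u / sqrt(sum(u^2))
    v <- c(t[2L] * u[3L] - t[3L] * u[2L],
           t[3L] * u[1L] - t[1L] * u[3L],
           t[1L] * u[2L] - t[2L] * u[1L])
    t <- t + rnorm(1L, sd = sdv) * u + rnorm(1L, sd = sdv) * v
    t <- t / sqrt(sum(t^2))
    nxt <- p[i, ] + step * t
    if (!is.null(box)) {
      for (d in 1:3) {
        if (nxt[d] < 0) { nxt[d] <- -nxt[d]; t[d] <- -t[d] }
        if (nxt[d] > box[d]) { nxt[d] <- 2 * box[d] - nxt[d]; t[d] <- -t[d] }
      }
    }
    p[i + 1L, ] <- nxt
  }
  p
}

min_dist_to <- function(p, q) {
  ## smallest distance from any row of p to any row of q (small n)
  if (!nrow(q)) return(Inf)
  mn <- Inf
  for (i in seq_len(nrow(p))) {
    d2 <- min(rowSums(sweep(q, 2L, p[i, ])^2))
    if (d2 < mn) mn <- d2
  }
  sqrt(mn)
}

#' Generate a ground-truth filament network and its snakes
#'
#' Primary filaments are sampled as discrete worm-like chains inside the
#' box.  A filament may carry one planted Y-junction: the chain is split at
#' a random interior vertex into two snakes and a branch chain is attached
#' whose first vertex lies within `junction_jitter` of the split vertex.
#' Emitted snakes therefore break exactly at planted junctions, and each
#' snake is one ground-truth segment with its own log-normal brightness.
#'
#' With `min_separation > 0` newly sampled chains keep that distance from
#' all previously placed vertices (outside planted-junction
#' neighbourhoods), so running [build_network()] with
#' `epsilon > 2 * junction_jitter` and `min_separation > 2 * epsilon`
#' recovers exactly the planted nodes.
#'
#' @param params a [synth_params].
#' @return List with `snakes` (a [snake_set]), `truth` (list: `nodes` data
#'   frame with position and planted degree, `segments` data frame with
#'   snake_id, length, brightness, azimuth, elevation, `total_length`,
#'   `n_nodes`) and `params`.
#' @export
generate_network <- function(params = synth_params()) {
  set.seed(params$seed)
  step <- params$step
  n_steps <- max(2L, round(params$filament_length / step))
  placed <- matrix(numeric(0), 0L, 3L)
  sep <- params$min_separation
  snakes <- list(); snake_id <- 0L
  truth_nodes <- list(); truth_segs <- list()
  add_snake <- function(p, brightness) {
    snake_id <<- snake_id + 1L
    snakes[[snake_id]] <<- data.frame(snake_id = snake_id,
                                      x = p[, 1L], y = p[, 2L], z = p[, 3L],
                                      intensity = brightness)
    ornt <- segment_orientation(p)
    truth_segs[[snake_id]] <<- data.frame(
      snake_id = snake_id, length = arc_length(p), brightness = brightness,
      azimuth = ornt[1L], elevation = ornt[2L])
  }
  add_node <- function(pos, degree) {
    truth_nodes[[length(truth_nodes) + 1L]] <<-
      data.frame(x = pos[1L], y = pos[2L], z = pos[3L], degree = degree)
  }
  sample_chain <- function(start_fun, t0 = NULL, attach = NULL) {
    for (try in 1:25) {
      p <- wlc_chain(n_steps, step, params$persistence_length,
                     start = start_fun(), t0 = t0, box = params$box)
      if (sep <= 0) return(p)
      ## ignore vertices inside the ball around an intended junction
      test <- p
      if (!is.null(attach))
        test <- p[row_norms(sweep(p, 2L, attach)) > 2 * sep / 2, , drop = FALSE]
      if (min_dist_to(test, placed) >= sep) return(p)
    }
    NULL
  }
  for (f in seq_len(params$n_filaments)) {
    p <- sample_chain(function() runif(3L) * params$box)
    if (is.null(p)) next
    placed <- rbind(placed, p)
    branch <- runif(1L) < params$branch_probability
    bright <- function() rlnorm(1L, params$brightness_meanlog,
                                params$brightness_sdlog)
    if (branch && n_steps >= 6L) {
      j <- sample(3:(n_steps - 2L), 1L)
      jpos <- p[j, ]
      add_snake(p[1:j, , drop = FALSE], bright())
      add_snake(p[j:nrow(p), , drop = FALSE], bright())
      off <- random_unit_vectors(1L)[1L, ] *
        runif(1L, 0, params$junction_jitter)
      ## branch transverse to the parent so the child clears the parent
      ## immediately (Y-branch geometry) and only the planted junction
      ## clusters
      tj <- p[j + 1L, ] - p[j - 1L, ]
      tj <- tj / sqrt(sum(tj^2))
      ref <- if (abs(tj[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * tj) * tj; u <- u / sqrt(sum(u^2))
      v <- c(tj[2L] * u[3L] - tj[3L] * u[2L],
             tj[3L] * u[1L] - tj[1L] * u[3L],
             tj[1L] * u[2L] - tj[2L] * u[1L])
      phi <- runif(1L, 0, 2 * pi)
      t0 <- cos(phi) * u + sin(phi) * v
      child <- sample_chain(function() jpos + off, t0 = t0, attach = jpos)
      if (!is.null(child)) {
        add_snake(child, bright())
        add_node(jpos, 3L)
        add_node(child[nrow(child), ], 1L)
        placed <- rbind(placed, child)
      } else add_node(jpos, 2L)
      add_node(p[1L, ], 1L)
      add_node(p[nrow(p), ], 1L)
    } else {
      add_snake(p, bright())
      add_node(p[1L, ], 1L)
      add_node(p[nrow(p), ], 1L)
    }
  }
  if (!length(snakes)) stop("no filaments could be placed", call. = FALSE)
  snakes_df <- do.call(rbind, snakes)
  truth <- list(nodes = do.call(rbind, truth_nodes),
                segments = do.call(rbind, truth_segs))
  truth$total_length <- sum(truth$segments$length)
  truth$n_nodes <- nrow(truth$nodes)
  list(snakes = snake_set(snakes_df), truth = truth, params = params)
}

#' Voxelize a network into a noisy fluorescence stack
#'
#' Snakes are resampled densely and deposited into the voxel grid with
#' amplitude proportional to brightness times deposited length, blurred by
#' an anisotropic Gaussian point-spread function, and degraded with noise
#' (additive Gaussian, optional Poisson shot noise).  Negative values are
#' clipped to zero.
#'
#' @param snakes a [snake_set] (e.g. from [generate_network()]).
#' @param params a [synth_params].
#' @param noise if `FALSE`, the noise-free signal is returned.
#' @return An [image_stack].
#' @export
voxelize <- function(snakes, params = synth_params(), noise = TRUE) {
  sp <- params$voxel_spacing                    # (z, y, x)
  dims <- c(ceiling(params$box[3L] / sp[1L]) + 1L,
            ceiling(params$box[2L] / sp[2L]) + 1L,
            ceiling(params$box[1L] / sp[3L]) + 1L)
  vox <- array(0, dim = dims)
  dep_step <- min(sp) / 2
  vox_vol <- prod(sp)
  for (s in snake_list(snakes)) {
    p <- as.matrix(s[, c("x", "y", "z")])
    r <- resample_polyline(p, dep_step)
    ## brightness acts as fluorophore line density (a.u. per um); voxel
    ## values are densities per um^3, keeping centreline intensities well
    ## above the default noise floor as in the source recordings
    amp <- mean(s$intensity) * arc_length(p) / nrow(r) / vox_vol
    iz <- pmin(dims[1L], pmax(1L, round(r[, 3L] / sp[1L]) + 1L))
    iy <- pmin(dims[2L], pmax(1L, round(r[, 2L] / sp[2L]) + 1L))
    ix <- pmin(dims[3L], pmax(1L, round(r[, 1L] / sp[3L]) + 1L))
    for (k in seq_len(nrow(r)))
      vox[iz[k], iy[k], ix[k]] <- vox[iz[k], iy[k], ix[k]] + amp
  }
  st <- image_stack(vox, sp)
  sig_px <- c(params$psf_sigma[1L] / sp[3L],    # x um -> x px
              params$psf_sigma[2L] / sp[2L],
              params$psf_sigma[3L] / sp[1L])
  st <- blur3d(st, sig_px)
  if (noise) {
    v <- st$voxels
    if (params$poisson_noise) v <- array(rpois(length(v), pmax(v, 0)), dim(v))
    v <- v + rnorm(length(v), sd = params$noise_sd)
    st <- image_stack(pmax(v, 0), sp)
  }
  st
}

straight_snake <- function(id, from, to, n = 11L, intensity = 50) {
  tt <- seq(0, 1, length.out = n)
  data.frame(snake_id = id,
             x = from[1L] + tt * (to[1L] - from[1L]),
             y = from[2L] + tt * (to[2L] - from[2L]),
             z = from[3L] + tt * (to[3L] - from[3L]),
             intensity = intensity)
}

#' Deterministic named fixtures covering the pipeline's regimes
#'
#' Writes a set of snake files plus ground-truth JSON into `dir`:
#'
#' * `isolated` — one straight filament (2 end nodes, 1 segment),
#' * `y_junction` — three snakes meeting at a point (one degree-3 node),
#' * `x_crossing` — two snakes crossing at interior vertices (degree-4),
#' * `star` — five snakes radiating from a point (degree-5),
#' * `parallel` — a polarized parallel bundle array dominated by a few long
#'   bundles (anisotropy index above 0.8, keratinocyte-like),
#' * `isotropic` — many randomly oriented short segments in a shell
#'   (anisotropy index below 0.05, simple-epithelium-like).
#'
#' @param dir output directory (created if needed).
#' @param scale `"tiny"` keeps the stochastic fixtures small; `"desk"` uses
#'   the sizes quoted in the ground truth bounds.
#' @param seed RNG seed for the stochastic fixtures.
#' @return Invisibly, a named list with `snakes` path, `truth` list and
#'   `truth_path` per fixture.
#' @export
fixture_suite <- function(dir, scale = c("desk", "tiny"), seed = 1L) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  eps <- graph_params()$epsilon
  j <- eps / 4                                  # junction jitter < eps/2
  fixtures <- list()
  emit <- function(name, df, truth) {
    sp <- file.path(dir, paste0(name, ".snakes.txt"))
    tp <- file.path(dir, paste0(name, ".truth.json"))
    write_snakes(snake_set(df), sp, "tsoax")
    jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
    fixtures[[name]] <<- list(snakes = sp, truth = truth, truth_path = tp)
  }
  emit("isolated", straight_snake(1, c(0, 0, 0), c(5, 0, 0)),
       list(n_nodes = 2, n_segments = 1, degrees = c(1, 1), total_length = 5))
  ## three arms ending within j of the common point
  ctr <- c(5, 5, 1)
  y3 <- rbind(straight_snake(1, ctr + c(-4, 0, 0), ctr + c(-j, 0, 0)),
              straight_snake(2, ctr + c(3, 3, 0), ctr + c(j, 0, 0)),
              straight_snake(3, ctr + c(3, -3, 0), ctr + c(0, j, 0)))
  emit("y_junction", y3,
       list(n_nodes = 4, n_segments = 3, degree_hist = list(`3` = 1),
            total_length = NA))
  x4 <- rbind(straight_snake(1, ctr + c(-4, -4, 0), ctr + c(4, 4, 0), n = 21),
              straight_snake(2, ctr + c(-4, 4, j), ctr + c(4, -4, j), n = 21))
  emit("x_crossing", x4,
       list(n_nodes = 5, n_segments = 4, degree_hist = list(`4` = 1),
            total_length = NA))
  arms <- lapply(1:5, function(k) {
    ang <- 2 * pi * (k - 1) / 5
    straight_snake(k, ctr + 4 * c(cos(ang), sin(ang), 0),
                   ctr + j / 2 * c(cos(ang), sin(ang), 0))
  })
  emit("star", do.call(rbind, arms),
       list(n_nodes = 6, n_segments = 5, degree_hist = list(`5` = 1),
            total_length = NA))
  ## polarized parallel array: many short filaments left, few long bundles
  ## right of the (segment-count weighted) cell centre, so nearly all arc
  ## length points +x after outward translocation
  shorts <- lapply(1:24, function(k)
    straight_snake(k, c(0, 0.4 * k, 0.5), c(0.2, 0.4 * k, 0.5), n = 3,
                   intensity = 20))
  longs <- lapply(1:4, function(k)
    straight_snake(24 + k, c(3, 2 + 1.5 * k, 0.5), c(23, 2 + 1.5 * k, 0.5),
                   n = 41, intensity = 120))
  emit("parallel", do.call(rbind, c(shorts, longs)),
       list(n_segments = 28, anisotropy_min = 0.8))
  ## isotropic shell of short segments around a centre
  n_iso <- if (scale == "desk") 1000L else 200L
  dirs <- random_unit_vectors(n_iso)
  mids <- random_unit_vectors(n_iso) * runif(n_iso, 4, 6)
  iso <- do.call(rbind, lapply(seq_len(n_iso), function(k)
    straight_snake(k, mids[k, ] - 0.4 * dirs[k, ], mids[k, ] + 0.4 * dirs[k, ],
                   n = 5)))
  emit("isotropic", iso,
       list(n_segments = n_iso, anisotropy_max = 0.05))
  invisible(fixtures)
}
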