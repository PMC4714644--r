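#' Simulation settings for a synthetic fMRI cohort
#'
#' Describes the synthetic study: a cohort of normal-hearing controls and
#' implant candidates (labeled effective / ineffective plus unlabeled), each
#' with a 3-D contrast t-map containing planted spherical regions whose mean
#' amplitude depends on the group. Noise is added voxelwise and the map is
#' smoothed with a separable Gaussian kernel, mimicking the spatial
#' autocorrelation of preprocessed t-maps.
#'
#' The default cohort matches the study design this package emulates:
#' 21 controls and 23 implant candidates (9 effective, 7 ineffective,
#' 7 unlabeled), 44 subjects in all. The default effect vectors make the two
#' planted regions complementary: region 1 responds strongly in effective
#' users (and controls), region 2 in ineffective users, so that neither
#' region alone separates the groups as well as the pair does.
#'
#' @param grid_shape Integer vector of 3 voxel counts per axis (each >= 8, so
#'   that 26-connectivity has room to act).
#' @param n_controls,n_effective,n_ineffective,n_unlabeled Subject counts.
#' @param region_centers List of voxel-coordinate centers (1-based) for the
#'   planted discriminative regions.
#' @param region_radius Sphere radius in voxels (>= 1); regions must lie
#'   fully inside the grid.
#' @param effect_effective,effect_ineffective,effect_control Mean t-amplitude
#'   inside the planted regions for each group, before smoothing. Length 1
#'   (same in every region) or one value per region.
#' @param noise_sd Standard deviation of the voxelwise Gaussian noise added
#'   before smoothing (t-units). The default of 5 together with the default
#'   2-voxel FWHM yields a post-smoothing marginal noise SD close to 1,
#'   matching a unit-variance t-map.
#' @param smoothing_fwhm Gaussian smoothing FWHM in voxels; 0 disables
#'   smoothing.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A `map_sim_config` list.
#' @export
map_sim_config <- function(grid_shape = c(24L, 24L, 24L),
                           n_controls = 21L, n_effective = 9L,
                           n_ineffective = 7L, n_unlabeled = 7L,
                           region_centers = list(c(7, 12, 12), c(17, 12, 12)),
                           region_radius = 3,
                           effect_effective = c(4, 1),
                           effect_ineffective = c(1, 4),
                           effect_control = c(4, 3),
                           noise_sd = 5, smoothing_fwhm = 2, seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), n_controls = n_controls,
              n_effective = n_effective, n_ineffective = n_ineffective,
              n_unlabeled = n_unlabeled, region_centers = region_centers,
              region_radius = region_radius,
              effect_effective = effect_effective,
              effect_ineffective = effect_ineffective,
              effect_control = effect_control, noise_sd = noise_sd,
              smoothing_fwhm = smoothing_fwhm, seed = as.integer(seed))
  validate_map_sim_config(cfg)
}

validate_map_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop_bowsvm(sprintf("invalid `%s`: %s", field, why), "bowsvm_config_error")
  }
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L))
    bad("grid_shape", "must be 3 integers, each >= 8")
  for (f in c("n_controls", "n_effective", "n_ineffective", "n_unlabeled")) {
    if (length(cfg[[f]]) != 1L || cfg[[f]] < 0) bad(f, "must be a count >= 0")
  }
  if (cfg$region_radius < 1) bad("region_radius", "must be >= 1")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (cfg$smoothing_fwhm < 0) bad("smoothing_fwhm", "must be >= 0")
  nr <- length(cfg$region_centers)
  for (ctr in cfg$region_centers) {
    if (length(ctr) != 3L) bad("region_centers", "each center needs 3 coords")
    if (any(ctr - cfg$region_radius < 1) ||
        any(ctr + cfg$region_radius > cfg$grid_shape))
      bad("region_centers", "planted region extends outside the grid")
  }
  for (f in c("effect_effective", "effect_ineffective", "effect_control")) {
    len <- length(cfg[[f]])
    if (len >= nr) cfg[[f]] <- cfg[[f]][seq_len(nr)]
    else if (len == 1L) cfg[[f]] <- rep_len(cfg[[f]], nr)
    else bad(f, sprintf("must have length 1 or %d (one per region)", nr))
  }
  structure(cfg, class = "map_sim_config")
}

# linear indices of a voxel sphere
sphere_indices <- function(grid_shape, center, radius) {
  rng <- lapply(1:3, function(a) {
    seq(max(1, floor(center[a] - radius)),
        min(grid_shape[a], ceiling(center[a] + radius)))
  })
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  as.integer(g$x + grid_shape[1] * (g$y - 1) +
               grid_shape[1] * grid_shape[2] * (g$z - 1))
}

#' Separable 3-D Gaussian smoothing
#'
#' Convolves each axis with a normalized 1-D Gaussian kernel (truncated at
#' 3 SD, zero-padded boundary). FWHM is in voxels.
#'
#' @param arr 3-D numeric array.
#' @param fwhm Full width at half maximum in voxels; 0 returns `arr`.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth_3d <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  smooth_axis1 <- function(a) {
    n <- dim(a)[1]
    kmat <- matrix(0, n, n)
    for (off in seq(-r, r)) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      kmat[cbind(i[ok], j[ok])] <- k[off + r + 1]
    }
    array(kmat %*% matrix(a, n, prod(dim(a)[-1])), dim = dim(a))
  }
  out <- smooth_axis1(arr)
  out <- aperm(smooth_axis1(aperm(out, c(2, 1, 3))), c(2, 1, 3))
  aperm(smooth_axis1(aperm(out, c(3, 2, 1))), c(3, 2, 1))
}

#' Generate a synthetic cohort of contrast maps
#'
#' One map per subject. Inside each planted region the pre-smoothing expected
#' value equals the subject group's effect amplitude for that region; outside
#' it is 0. Voxelwise Gaussian noise is added, then the map is smoothed.
#' Unlabeled subjects carry a latent group (recorded in the manifest) drawn
#' so that about 4/7 of them are effective-like, matching the positive ratio
#' the labeled cohort suggests.
#'
#' @param cfg A [map_sim_config()].
#' @param contrast_name Contrast label attached to every map.
#' @return A `cohort_maps` object: `maps` (named list of [contrast_map()]),
#'   `manifest` (tibble with `subject_id`, `group`, `labeled`, `latent`),
#'   `regions` (list of linear-index vectors of the planted regions), and
#'   the `config`.
#' @export
generate_cohort_maps <- function(cfg = map_sim_config(),
                                 contrast_name = "speech_vs_silence") {
  stopifnot(inherits(cfg, "map_sim_config"))
  gs <- cfg$grid_shape
  regions <- lapply(cfg$region_centers, sphere_indices,
                    grid_shape = gs, radius = cfg$region_radius)

  n_unl_pos <- round_half_up(4 / 7 * cfg$n_unlabeled)
  manifest <- tibble::tibble(
    subject_id = c(sprintf("ctrl%02d", seq_len(cfg$n_controls)),
                   sprintf("eff%02d", seq_len(cfg$n_effective)),
                   sprintf("ineff%02d", seq_len(cfg$n_ineffective)),
                   sprintf("unl%02d", seq_len(cfg$n_unlabeled))),
    group = c(rep("control", cfg$n_controls),
              rep("effective", cfg$n_effective),
              rep("ineffective", cfg$n_ineffective),
              rep("unlabeled", cfg$n_unlabeled)),
    labeled = .data$group %in% c("effective", "ineffective"),
    latent = c(rep("control", cfg$n_controls),
               rep("effective", cfg$n_effective),
               rep("ineffective", cfg$n_ineffective),
               c(rep("effective", n_unl_pos),
                 rep("ineffective", cfg$n_unlabeled - n_unl_pos)))
  )

  effects <- list(control = rep_len(cfg$effect_control, length(regions)),
                  effective = rep_len(cfg$effect_effective, length(regions)),
                  ineffective = rep_len(cfg$effect_ineffective, length(regions)))

  set.seed(cfg$seed)
  maps <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    eff <- effects[[manifest$latent[i]]]
    v <- array(0, dim = gs)
    for (j in seq_along(regions)) v[regions[[j]]] <- eff[j]
    if (cfg$noise_sd > 0) v <- v + array(rnorm(prod(gs), 0, cfg$noise_sd), gs)
    v <- gaussian_smooth_3d(v, cfg$smoothing_fwhm)
    maps[[i]] <- contrast_map(v, manifest$subject_id[i], contrast_name)
  }
  names(maps) <- manifest$subject_id
  structure(list(maps = maps, manifest = manifest, regions = regions,
                 config = cfg),
            class = "cohort_maps")
}

#' @export
print.cohort_maps <- function(x, ...) {
  cat("<cohort_maps>", length(x$maps), "subjects on a",
      paste(x$config$grid_shape, collapse = "x"), "grid\n")
  print(dplyr::count(x$manifest, .data$group))
  invisible(x)
}
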