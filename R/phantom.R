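make_region_voxel <- function(family, grid, reg, vseed) {
  switch(family,
    cylinders = make_cylinder_voxel(grid,
      radius_law = local({
        rr <- reg$radius
        function(k) rlnorm(k, log(rr), 0.2)
      }),
      target_bvf = reg$bvf, seed = vseed
    ),
    disks = make_disk_voxel(grid, reg$radius, reg$bvf, seed = vseed),
    network = grow_network_voxel(grid, network_params(
      target_bvf = reg$bvf,
      radius_law = local({
        rr <- reg$radius
        function(k) rlnorm(k, log(rr), 0.2)
      }),
      seed = vseed
    ))
  )
}

#' Simulate a multi-region fingerprint phantom
#'
#' Builds a synthetic fingerprint image through the full forward chain: each
#' image voxel gets its own microvascular geometry realization at its
#' region's target (BVf, R), the pre/post-contrast GESFIDSE signals are
#' simulated, white Gaussian noise is added to the raw samples before
#' normalization, and the concatenated fingerprints are assembled into a
#' series. The default two-region layout emulates a "tumour" patch with
#' elevated blood volume and oxygenation inside "contralateral" tissue. The
#' ground truth records both the nominal region parameters and the measured
#' (BVf, R) of every realized geometry.
#'
#' @param regions tibble with columns `region`, `bvf`, `radius`, `so2`, `t2`
#'   (one row per region, region ids matching `region_map`).
#' @param region_map integer matrix assigning a region id to every image
#'   voxel. Default: an 8 x 8 image whose central 4 x 4 block is region 2.
#' @param snr signal-to-noise ratio, defined on the first pre-contrast echo
#'   of the raw (unnormalized) signal; `Inf` for noiseless.
#' @param grid micro-scale [grid_spec()] of the per-voxel geometries.
#' @param seq,physics forward-model settings.
#' @param family geometry family used for the realizations.
#' @param seed integer seed (phantoms are deterministic given it).
#' @param dict_ranges optional named list of dictionary parameter ranges; a
#'   warning (not an error) is raised when region parameters fall outside,
#'   since the learning-based reconstruction then extrapolates.
#' @return A `vmrf_phantom`: `series` (`nx x ny x 2 n_echoes` array),
#'   `truth` (tibble per voxel), `region_map`, `regions`, `snr`.
#' @export
make_phantom <- function(regions,
                         region_map = NULL,
                         snr = Inf,
                         grid = grid_spec(c(32, 32, 48), 2.5),
                         seq = sequence_spec(),
                         physics = physics_constants(),
                         family = c("cylinders", "disks", "network"),
                         seed = 1L,
                         dict_ranges = NULL) {
  family <- match.arg(family)
  regions <- as_tibble(regions)
  need <- c("region", "bvf", "radius", "so2", "t2")
  if (!all(need %in% names(regions))) {
    abort(paste0("`regions` needs columns: ", paste(need, collapse = ", ")))
  }
  if (is.null(region_map)) {
    region_map <- matrix(1L, 8, 8)
    region_map[3:6, 3:6] <- 2L
  }
  if (!all(unique(as.vector(region_map)) %in% regions$region)) {
    abort("every region id in `region_map` needs a row in `regions`.")
  }
  if (!is.null(dict_ranges)) {
    for (p in intersect(names(dict_ranges), c("bvf", "radius", "so2", "t2"))) {
      rr <- dict_ranges[[p]]
      if (any(regions[[p]] < rr[1] | regions[[p]] > rr[2])) {
        warn(sprintf(
          "region %s values fall outside the dictionary range [%g, %g]; DBL will extrapolate",
          p, rr[1], rr[2]
        ))
      }
    }
  }
  nx <- nrow(region_map)
  ny <- ncol(region_map)
  flen <- 2L * seq$n_echoes
  series <- array(NA_real_, c(nx, ny, flen))
  truth <- tibble(
    x = rep(seq_len(nx), ny), y = rep(seq_len(ny), each = nx),
    region = as.integer(region_map[cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))]),
    bvf_nominal = NA_real_, radius_nominal = NA_real_,
    bvf = NA_real_, radius = NA_real_, so2 = NA_real_, t2 = NA_real_
  )
  voxel_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, nx * ny))
  for (i in seq_len(nx * ny)) {
    reg <- regions[match(truth$region[i], regions$region), ]
    # a realization attempt can be geometrically infeasible (the BVf band is
    # quantized by whole structures); retry with a fresh derived seed
    v <- NULL
    for (attempt in 0:20) {
      v <- tryCatch(
        make_region_voxel(family, grid, reg, voxel_seeds[i] + 31L * attempt),
        error = function(e) e
      )
      if (!inherits(v, "error")) break
    }
    if (inherits(v, "error")) {
      abort(sprintf(
        "could not realize a voxel for region %s: %s",
        truth$region[i], conditionMessage(v)
      ))
    }
    fp_clean <- simulate_fingerprint(v, reg$so2, reg$t2, seq, physics)
    raw <- fp_clean$values * fp_clean$norm
    if (is.finite(snr)) {
      noise_sd <- raw[1] / snr
      raw <- with_seed(voxel_seeds[i] + 1, raw + rnorm(length(raw), 0, noise_sd))
      raw <- abs(raw) # acquired fingerprints are magnitude data
    }
    fp <- make_fingerprint(raw[seq_len(seq$n_echoes)], raw[-seq_len(seq$n_echoes)])
    xy <- c(truth$x[i], truth$y[i])
    series[xy[1], xy[2], ] <- fp$values
    truth$bvf_nominal[i] <- reg$bvf
    truth$radius_nominal[i] <- reg$radius
    truth$bvf[i] <- v$bvf
    truth$radius[i] <- v$mean_radius
    truth$so2[i] <- reg$so2
    truth$t2[i] <- reg$t2
  }
  structure(
    list(
      series = series, truth = truth, region_map = region_map,
      regions = regions, snr = snr, seed = seed, family = family
    ),
    class = "vmrf_phantom"
  )
}

#' @export
print.vmrf_phantom <- function(x, ...) {
  cat(sprintf(
    "<vmrf_phantom> %d x %d voxels, %d regions, SNR %s (%s family)\n",
    nrow(x$region_map), ncol(x$region_map), nrow(x$regions),
    if (is.finite(x$snr)) format(x$snr) else "Inf", x$family
  ))
  invisible(x)
}
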