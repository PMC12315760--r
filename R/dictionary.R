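#' Generate a set of voxel geometries for one dictionary family
#'
#' Builds `n` voxel geometries of the requested family. Targets for blood
#' volume fraction and radius are themselves Sobol-distributed over their
#' ranges so the (BVf, R) plane is covered evenly, mirroring the coverage of
#' the vascular parameter space by a dictionary; the parameter table of the
#' resulting dictionary records the measured values, not the targets.
#'
#' @param n number of geometries.
#' @param family `"cylinders"` (3D-synth), `"disks"` (2D-synth) or
#'   `"network"` (stochastic realistic-like).
#' @param grid the [grid_spec()] all voxels share.
#' @param bvf_range,radius_range target ranges, percent and micrometres.
#' @param seed integer seed (each voxel gets an independent derived seed).
#' @return A list of `vmrf_voxel` objects of length `n`.
#' @export
generate_geometry_set <- function(n, family = c("cylinders", "disks", "network"),
                                  grid = NULL,
                                  bvf_range = c(0.5, 12),
                                  radius_range = c(2, 10),
                                  seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- if (family == "disks") {
      grid_spec(c(64, 64, 1), 2.5)
    } else {
      grid_spec(c(32, 32, 48), 2.5)
    }
  }
  targets <- sobol_sample(
    n,
    ranges = list(bvf = bvf_range, radius = radius_range),
    seed = seed
  )
  voxel_seeds <- with_seed(seed + 1L, sample.int(.Machine$integer.max - 1L, n))
  build_one <- function(b, r, vseed) {
    switch(family,
      disks = make_disk_voxel(grid, radius = r, target_bvf = b, seed = vseed),
      cylinders = make_cylinder_voxel(
        grid,
        radius_law = local({
          rr <- r
          function(k) rlnorm(k, log(rr), 0.2)
        }),
        target_bvf = b, seed = vseed
      ),
      network = grow_network_voxel(grid, network_params(
        target_bvf = b,
        radius_law = local({
          rr <- r
          function(k) rlnorm(k, log(rr), 0.2)
        }),
        seed = vseed
      ))
    )
  }
  purrr::map(seq_len(n), function(i) {
    # not every (BVf, R) pair is geometrically feasible (realized BVf is
    # quantized by whole structures at large radii, and vessels thinner than
    # the min-Feret area threshold leave the mean radius undefined);
    # infeasible targets are re-drawn so the set keeps its nominal size
    b <- targets$bvf[i]
    r <- targets$radius[i]
    for (attempt in 0:20) {
      v <- tryCatch(
        build_one(b, r, voxel_seeds[i] + attempt),
        error = function(e) e
      )
      if (!inherits(v, "error") && is.na(v$mean_radius)) {
        v <- simpleError("mean radius undefined (all cross-sections below the area threshold)")
      }
      if (!inherits(v, "error")) return(v)
      redraw <- with_seed(voxel_seeds[i] + 7919L * (attempt + 1L), {
        c(runif(1, bvf_range[1], bvf_range[2]), runif(1, radius_range[1], radius_range[2]))
      })
      b <- redraw[1]
      r <- redraw[2]
    }
    abort(sprintf("could not realize a feasible geometry for entry %d", i))
  })
}

#' Build a fingerprint dictionary
#'
#' Runs the forward chain over a set of voxel geometries: for each geometry
#' one unit-susceptibility dipole solve, two GESFIDSE simulations (pre
#' contrast, `dchi_ca = 0`, and post contrast), and one concatenated
#' L2-normalized fingerprint. One (SO2, T2) sample is attributed to each
#' geometry. The parameter table records the geometry's measured BVf and
#' mean radius together with the sampled SO2 and T2.
#'
#' @param geometries list of `vmrf_voxel` objects.
#' @param samples tibble with columns `so2` and `t2`, one row per geometry
#'   (e.g. from [sobol_sample()]).
#' @param seq a [sequence_spec()].
#' @param physics a [physics_constants()] bundle.
#' @param family tag recorded in the metadata.
#' @param seed seed recorded in the metadata (the build itself is
#'   deterministic given its inputs).
#' @param progress print a progress line every 200 entries.
#' @return A `vmrf_dictionary`: `params` (tibble: voxel_id, bvf, radius,
#'   so2, t2), `signals` (row-aligned matrix of unit-norm fingerprints),
#'   `norms`, `meta`.
#' @export
build_dictionary <- function(geometries, samples, seq = sequence_spec(),
                             physics = physics_constants(),
                             family = NULL, seed = NA_integer_,
                             progress = FALSE) {
  n <- length(geometries)
  if (nrow(samples) != n) {
    abort(sprintf(
      "need one (so2, t2) sample per geometry: %d geometries, %d samples",
      n, nrow(samples)
    ))
  }
  if (any(duplicated(data.frame(i = seq_len(n), samples$so2, samples$t2)))) {
    abort("duplicate (voxel, so2, t2) triples")
  }
  len <- 2L * seq$n_echoes
  signals <- matrix(NA_real_, n, len)
  norms <- numeric(n)
  params <- tibble(
    voxel_id = seq_len(n),
    bvf = NA_real_, radius = NA_real_,
    so2 = samples$so2, t2 = samples$t2
  )
  for (i in seq_len(n)) {
    v <- geometries[[i]]
    fp <- tryCatch(
      simulate_fingerprint(v, samples$so2[i], samples$t2[i], seq, physics),
      error = function(e) {
        abort(sprintf("simulation failed for voxel_id %d: %s", i, conditionMessage(e)))
      }
    )
    signals[i, ] <- fp$values
    norms[i] <- fp$norm
    params$bvf[i] <- v$bvf
    params$radius[i] <- v$mean_radius
    if (progress && i %% 200L == 0L) {
      message(sprintf("  dictionary entry %d / %d", i, n))
    }
  }
  structure(
    list(
      params = params, signals = signals, norms = norms,
      meta = list(
        family = family %||% geometries[[1]]$provenance,
        n_entries = n, seq = seq, physics = physics, seed = seed,
        grid = geometries[[1]]$grid,
        created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
        container_version = 1L
      )
    ),
    class = "vmrf_dictionary"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vmrf_dictionary <- function(x, ...) {
  cat(sprintf(
    "<vmrf_dictionary> %d entries (%s family), %d-sample fingerprints\n",
    nrow(x$params), x$meta$family, ncol(x$signals)
  ))
  print(head(x$params, 4))
  invisible(x)
}

#' @rdname build_dictionary
#' @param x a `vmrf_dictionary`.
#' @export
tidy.vmrf_dictionary <- function(x, ...) x$params

#' Save / load a fingerprint dictionary
#'
#' One dictionary per file, in a versioned single-file container holding the
#' parameter table, the signal matrix, the raw norms and the full metadata
#' (sequence spec, physics constants, family tag, seed, creation log).
#' Round-trips are lossless. Files with a different container version or
#' inconsistent row counts are refused.
#'
#' @param d a `vmrf_dictionary`.
#' @param path file path (conventionally `.vdict`).
#' @return `save_dictionary` returns `path` invisibly; `load_dictionary`
#'   returns the `vmrf_dictionary`.
#' @export
save_dictionary <- function(d, path) {
  if (!inherits(d, "vmrf_dictionary")) abort("`d` must be a vmrf_dictionary.")
  payload <- list(
    container = "vascmrf-dictionary",
    version = 1L,
    params = d$params, signals = d$signals, norms = d$norms, meta = d$meta
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) abort(sprintf("dictionary file not found: %s", path))
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("cannot read dictionary container %s: %s", path, conditionMessage(e)))
  })
  if (!identical(payload$container, "vascmrf-dictionary")) {
    abort(sprintf("%s is not a vascmrf dictionary container", path))
  }
  if (!identical(payload$version, 1L)) {
    abort(sprintf("unsupported dictionary container version: %s", payload$version))
  }
  if (nrow(payload$params) != nrow(payload$signals)) {
    abort("corrupt dictionary: parameter and signal row counts differ")
  }
  structure(
    list(
      params = payload$params, signals = payload$signals,
      norms = payload$norms, meta = payload$meta
    ),
    class = "vmrf_dictionary"
  )
}

#' Build a cylinder- or disk-family dictionary in one call
#'
#' Convenience wrapper: generates the geometry set, Sobol-samples (SO2, T2),
#' and runs [build_dictionary()].
#'
#' @inheritParams generate_geometry_set
#' @inheritParams build_dictionary
#' @param so2_range,t2_range sampling ranges for SO2 (percent) and T2 (ms).
#' @export
make_dictionary <- function(n, family = c("cylinders", "disks", "network"),
                            grid = NULL,
                            bvf_range = c(0.5, 12), radius_range = c(2, 10),
                            so2_range = c(35, 90), t2_range = c(45, 110),
                            seq = sequence_spec(),
                            physics = physics_constants(),
                            seed = 1L, progress = FALSE) {
  family <- match.arg(family)
  geoms <- generate_geometry_set(
    n, family, grid, bvf_range, radius_range,
    seed = seed
  )
  samples <- sobol_sample(
    n,
    ranges = list(so2 = so2_range, t2 = t2_range), seed = seed + 1000L
  )
  build_dictionary(geoms, samples, seq, physics,
    family = family, seed = seed,
    progress = progress
  )
}
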