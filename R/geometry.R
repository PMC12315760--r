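#' Voxel geometry container
#'
#' A voxel-scale vascular occupancy volume: a binary 3D array (1 =
#' intravascular) on a [grid_spec()] grid, an integer vessel-segment label
#' array, the blood volume fraction realized by the mask, and the mean vessel
#' radius measured by [characterize_voxel()]. Constructed by the generators
#' ([make_disk_voxel()], [make_cylinder_voxel()], [grow_network_voxel()]) or
#' from a user-supplied mask.
#'
#' @param occupancy logical/integer 3D array (or matrix for 2D voxels).
#' @param grid a [grid_spec()]; its shape must match `dim(occupancy)`.
#' @param labels optional integer array of the same shape assigning each
#'   intravascular cell to a vessel segment (0 = extravascular).
#' @param provenance tag recording how the mask was produced.
#' @param characterize if `TRUE` (default), measure mean radius immediately.
#'
#' @return A `vmrf_voxel` object with fields `grid`, `occupancy` (integer
#'   array), `labels`, `bvf` (percent), `mean_radius` (micrometres, `NA` if
#'   the mask is empty), `provenance`.
#' @export
voxel_geometry <- function(occupancy, grid, labels = NULL,
                           provenance = "user", characterize = TRUE) {
  if (is.matrix(occupancy)) dim(occupancy) <- c(dim(occupancy), 1L)
  if (!identical(dim(occupancy), as.integer(grid$shape))) {
    abort("`occupancy` dimensions must match `grid$shape`.")
  }
  occ <- array(as.integer(occupancy != 0), dim = grid$shape)
  if (is.null(labels)) {
    labels <- occ
  } else {
    if (is.matrix(labels)) dim(labels) <- c(dim(labels), 1L)
    labels <- array(as.integer(labels), dim = grid$shape)
  }
  v <- structure(
    list(
      grid = grid, occupancy = occ, labels = labels,
      bvf = 100 * sum(occ) / n_cells(grid),
      mean_radius = NA_real_, provenance = provenance
    ),
    class = "vmrf_voxel"
  )
  if (characterize && v$bvf > 0) {
    ch <- characterize_voxel(v)
    v$mean_radius <- ch$mean_radius
  }
  v
}

#' @export
print.vmrf_voxel <- function(x, ...) {
  cat(sprintf(
    "<vmrf_voxel> [%s] %d x %d x %d cells, BVf %.3f%%, mean radius %s um\n",
    x$provenance, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], x$bvf,
    if (is.na(x$mean_radius)) "NA" else sprintf("%.2f", x$mean_radius)
  ))
  invisible(x)
}

# tolerance band for realized vs target BVf (percentage points)
bvf_tolerance <- function(target_bvf) max(0.05, 0.02 * target_bvf)

# Sequentially add shapes until bvf is inside the tolerance band around the
# target; a stamp that overshoots the band is undone (its label reset) and
# redrawn, up to `max_retries` times.
add_until_bvf <- function(lab, grid, target_bvf, stamp_one, max_retries = 200L) {
  total <- n_cells(grid)
  tol <- bvf_tolerance(target_bvf)
  occupied <- sum(lab != 0L)
  label <- max(lab)
  retries <- 0L
  while (100 * occupied / total < target_bvf - tol) {
    label <- label + 1L
    added <- stamp_one(lab, label)
    new_bvf <- 100 * (occupied + added) / total
    if (new_bvf > target_bvf + tol) {
      lab[lab == label] <- 0L # reject: overshoot beyond the band
      label <- label - 1L
      retries <- retries + 1L
      if (retries > max_retries) {
        abort(sprintf(
          paste0(
            "cannot reach target BVf %.3f%% +/- %.3f pp: structures of the ",
            "requested size overshoot the band (reached %.3f%%); use smaller ",
            "radii or a larger tolerance band"
          ),
          target_bvf, tol, 100 * occupied / total
        ))
      }
    } else {
      occupied <- occupied + added
    }
  }
  lab
}

#' Generate a 2D disk voxel
#'
#' Places disks of a single fixed radius at uniform random positions (with
#' periodic wrap at the voxel edges) until the realized blood volume fraction
#' is within tolerance of the target. Overlapping disks are unioned. This is
#' the voxel model of the 2D-synth dictionary family.
#'
#' @param grid a 2D [grid_spec()] (`shape[3] == 1`).
#' @param radius disk radius in micrometres.
#' @param target_bvf target blood volume fraction in percent. The realized
#'   value satisfies `|realized - target| <= max(0.05 pp, 2\% relative)`.
#' @param seed integer seed; the generator is bitwise deterministic given it.
#' @return A `vmrf_voxel` with provenance `"disk2d"`.
#' @examples
#' v <- make_disk_voxel(grid_spec(c(64, 64, 1), 2), radius = 5, target_bvf = 3, seed = 1)
#' v$bvf
#' @export
make_disk_voxel <- function(grid, radius, target_bvf, seed = 1L) {
  if (!is_2d_grid(grid)) abort("`grid` must be 2D (nz = 1) for disk voxels.")
  if (radius <= 0) abort("`radius` must be positive.")
  area_frac <- 100 * pi * radius^2 / (grid$extent[1] * grid$extent[2])
  if (target_bvf > 0 && area_frac > target_bvf + bvf_tolerance(target_bvf)) {
    abort(sprintf(
      "one disk of radius %g um already fills %.3f%% of the plane; achievable targets are 0 or >= %.3f%%",
      radius, area_frac, area_frac - bvf_tolerance(area_frac)
    ))
  }
  lab <- with_seed(seed, {
    lab <- array(0L, grid$shape)
    if (target_bvf > 0) {
      lab <- add_until_bvf(lab, grid, target_bvf, function(lab, label) {
        p0 <- c(runif(1, 0, grid$extent[1]), runif(1, 0, grid$extent[2]), 0)
        .stamp_disk(lab, grid$shape, grid$spacing, p0, radius, label)
      })
    }
    lab
  })
  voxel_geometry(lab != 0L, grid, labels = lab, provenance = "disk2d")
}

# isotropic random unit vector
runif_sphere <- function() {
  z <- runif(1, -1, 1)
  phi <- runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(phi), s * sin(phi), z)
}

#' Generate a 3D cylinder voxel
#'
#' Fills a 3D voxel with straight infinite cylinders, isotropically oriented,
#' with radii drawn from `radius_law`, positions uniform, periodic wrap, until
#' the realized blood volume fraction is within tolerance of the target.
#' Overlaps are unioned. This is the voxel model of the 3D-synth dictionary
#' family.
#'
#' @param grid a 3D [grid_spec()].
#' @param radius_law either a single radius in micrometres or a function
#'   `function(n)` returning `n` radii.
#' @param target_bvf target blood volume fraction in percent (tolerance as in
#'   [make_disk_voxel()]).
#' @param seed integer seed.
#' @return A `vmrf_voxel` with provenance `"cylinder3d"`.
#' @examples
#' g <- grid_spec(c(32, 32, 48), 2.5)
#' v <- make_cylinder_voxel(g, radius_law = 5, target_bvf = 4, seed = 7)
#' c(v$bvf, v$mean_radius)
#' @export
make_cylinder_voxel <- function(grid, radius_law, target_bvf, seed = 1L) {
  if (is_2d_grid(grid)) abort("`grid` must be 3D for cylinder voxels.")
  draw_r <- if (is.function(radius_law)) radius_law else function(n) rep(radius_law, n)
  half_extent <- min(grid$extent) / 2
  lab <- with_seed(seed, {
    lab <- array(0L, grid$shape)
    if (target_bvf > 0) {
      lab <- add_until_bvf(lab, grid, target_bvf, function(lab, label) {
        r <- draw_r(1)
        if (r >= half_extent) {
          abort(sprintf(
            "radius_law drew %g um >= half the grid extent (%g um)", r, half_extent
          ))
        }
        p0 <- runif(3) * grid$extent
        u <- runif_sphere()
        .stamp_cylinder(lab, grid$shape, grid$spacing, p0, u, r, label)
      })
    }
    lab
  })
  voxel_geometry(lab != 0L, grid, labels = lab, provenance = "cylinder3d")
}

#' Stochastic vascular network parameters
#'
#' Controls for [grow_network_voxel()], the stochastic stand-in for
#' microscopy-derived vascular voxels: tortuous, branching tubular segments
#' grown as persistent random walks and rasterized as capsules.
#'
#' @param target_bvf target blood volume fraction, percent, in (0, 100).
#' @param radius_law function `function(n)` drawing segment radii (um), or a
#'   single radius. Default: lognormal with median 4 um, sdlog 0.3.
#' @param branching_rate expected branches per micrometre of grown centreline.
#' @param tortuosity_scale standard deviation of the per-step direction
#'   perturbation (radians per sqrt(10 um) of path); 0 gives straight tubes.
#' @param segment_length_law function `function(n)` drawing segment lengths
#'   (um), or a single length. Default: uniform on (40, 120) um.
#' @param seed integer seed.
#' @return A `vmrf_network_params` list.
#' @export
network_params <- function(target_bvf = 4,
                           radius_law = function(n) rlnorm(n, log(4), 0.3),
                           branching_rate = 0.02,
                           tortuosity_scale = 0.35,
                           segment_length_law = function(n) runif(n, 40, 120),
                           seed = 1L) {
  if (target_bvf <= 0 || target_bvf >= 100) abort("`target_bvf` must be in (0, 100).")
  structure(
    list(
      target_bvf = target_bvf,
      radius_law = if (is.function(radius_law)) radius_law else local({
        r <- radius_law
        function(n) rep(r, n)
      }),
      branching_rate = branching_rate,
      tortuosity_scale = tortuosity_scale,
      segment_length_law = if (is.function(segment_length_law)) segment_length_law else local({
        l <- segment_length_law
        function(n) rep(l, n)
      }),
      seed = as.integer(seed)
    ),
    class = "vmrf_network_params"
  )
}

#' Grow a stochastic branching vascular network voxel
#'
#' Grows tortuous, branching tubular segments (persistent random walks
#' rasterized as capsule chains with periodic wrap) until the realized blood
#' volume fraction is within tolerance of the target. Each segment gets its
#' own label, so the distributed-oxygenation mode of [susceptibility_map()]
#' can attribute per-vessel SO2 values. This generator emulates voxels whose
#' blood volume and radius statistics resemble microscopy-derived cortical
#' networks; it does not reproduce their anatomy.
#'
#' @param grid a 3D [grid_spec()].
#' @param params a [network_params()] object.
#' @return A `vmrf_voxel` with provenance `"network3d"` and per-segment labels.
#' @export
grow_network_voxel <- function(grid, params) {
  if (is_2d_grid(grid)) abort("`grid` must be 3D for network voxels.")
  if (!inherits(params, "vmrf_network_params")) abort("`params` must come from network_params().")
  step_len <- 2 * min(grid$spacing)
  total <- n_cells(grid)
  tol <- bvf_tolerance(params$target_bvf)

  with_seed(params$seed, {
    lab <- array(0L, grid$shape)
    occupied <- 0L
    label <- 0L
    retries <- 0L
    max_retries <- 200L
    centrelines <- list()
    while (100 * occupied / total < params$target_bvf - tol) {
      # grow one tree (trunk + stochastic branches); queue of (pos, dir, radius)
      start <- runif(3) * grid$extent
      queue <- list(list(p = start, u = runif_sphere(), r = params$radius_law(1)))
      tree_labels <- integer(0)
      tree_added <- 0L
      tree_paths <- list()
      overshoot <- FALSE
      done <- FALSE
      while (length(queue) > 0 && !overshoot && !done) {
        seg <- queue[[1]]
        queue <- queue[-1]
        label <- label + 1L
        tree_labels <- c(tree_labels, label)
        len <- params$segment_length_law(1)
        nsteps <- max(2L, ceiling(len / step_len))
        p <- seg$p
        u <- seg$u
        r <- max(seg$r, 0.75 * min(grid$spacing))
        path <- matrix(p, 1, 3)
        for (s in seq_len(nsteps)) {
          if (params$tortuosity_scale > 0) {
            pert <- rnorm(3, 0, params$tortuosity_scale * sqrt(step_len / 10))
            u <- u + pert
            u <- u / sqrt(sum(u^2))
          }
          q <- p + step_len * u
          added <- .stamp_capsule(lab, grid$shape, grid$spacing, p, q, r, label)
          tree_added <- tree_added + added
          occupied_now <- occupied + tree_added
          if (100 * occupied_now / total > params$target_bvf + tol) {
            overshoot <- TRUE # a single capsule jumped past the band
            break
          }
          if (100 * occupied_now / total >= params$target_bvf - tol) {
            # the running BVf entered the band: stop growing, keep the tree
            done <- TRUE
            p <- q
            path <- rbind(path, p)
            break
          }
          p <- q
          path <- rbind(path, p)
          if (runif(1) < params$branching_rate * step_len) {
            queue <- c(queue, list(list(
              p = p, u = runif_sphere(), r = 0.8 * r
            )))
          }
        }
        tree_paths[[length(tree_paths) + 1]] <- path
      }
      if (overshoot) {
        lab[lab %in% tree_labels] <- 0L # reject the whole tree
        label <- label - length(tree_labels)
        retries <- retries + 1L
        if (retries > max_retries) {
          abort(sprintf(
            "network growth failed: cannot reach BVf %.3f%% +/- %.3f pp after %d retries",
            params$target_bvf, tol, max_retries
          ))
        }
      } else {
        occupied <- occupied + tree_added
        centrelines <- c(centrelines, tree_paths)
      }
    }
    out <- voxel_geometry(lab != 0L, grid, labels = lab, provenance = "network3d")
    attr(out, "centrelines") <- centrelines
    out
  })
}

#' Erode a voxel geometry
#'
#' Applies morphological erosion with a 6-connected (3D cross) structuring
#' element `steps` times, with periodic boundary handling. Used to augment a
#' geometry set towards lower blood volume fractions and thinner vessels;
#' blood volume fraction is non-increasing in `steps`. For 2D voxels the
#' z-neighbours coincide with the cell itself under periodic wrap, so the
#' element reduces to the 4-connected in-plane cross.
#'
#' @param v a `vmrf_voxel`.
#' @param steps number of erosion passes (>= 0). Eroding to an empty mask is
#'   legal; the result then carries `bvf = 0` and `mean_radius = NA`.
#' @return An eroded `vmrf_voxel` with provenance `"eroded"` (or `v` itself
#'   for `steps = 0`).
#' @export
erode_voxel <- function(v, steps) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 0L) abort("`steps` must be a non-negative integer.")
  if (steps == 0L) return(v)
  occ <- v$occupancy
  d <- dim(occ)
  shift <- function(a, axis, by) {
    n <- d[axis]
    idx <- ((seq_len(n) - 1 + by) %% n) + 1
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
  }
  for (s in seq_len(steps)) {
    occ <- occ &
      shift(occ, 1L, 1L) & shift(occ, 1L, -1L) &
      shift(occ, 2L, 1L) & shift(occ, 2L, -1L) &
      shift(occ, 3L, 1L) & shift(occ, 3L, -1L)
  }
  occ <- array(as.integer(occ), d)
  out <- voxel_geometry(occ, v$grid,
    labels = v$labels * occ,
    provenance = "eroded", characterize = FALSE
  )
  if (out$bvf == 0) {
    warn("erosion produced an empty mask")
  } else {
    out$mean_radius <- characterize_voxel(out)$mean_radius
  }
  out
}

# min-Feret diameter (um) of one 2D connected component given its cell
# indices; cells contribute their 4 corners so the caliper sees pixel extent.
min_feret_diameter <- function(ix, iy, hx, hy, n_angles = 90L) {
  cx <- ix * hx
  cy <- iy * hy
  px <- c(cx - hx / 2, cx + hx / 2, cx - hx / 2, cx + hx / 2)
  py <- c(cy - hy / 2, cy - hy / 2, cy + hy / 2, cy + hy / 2)
  hull <- grDevices::chull(px, py)
  theta <- seq(0, pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  proj <- cbind(px[hull], py[hull]) %*% rbind(cos(theta), sin(theta))
  widths <- apply(proj, 2, max) - apply(proj, 2, min)
  min(widths)
}

#' Measure blood volume fraction and mean vessel radius
#'
#' BVf is the occupied-cell fraction times 100 (exact). The mean radius is
#' half the mean minimum Feret diameter of vessel cross-sections: each z-slice
#' is labelled into 2D connected components, components with at least
#' `min_area` cells are measured (the minimum caliper width of the pixel
#' corners), and the plain mean over all detections across slices is taken.
#' The minimum Feret diameter of a tilted vessel's elliptical cross-section is
#' its short axis, i.e. the true vessel diameter regardless of in-plane tilt.
#'
#' @param v a `vmrf_voxel`.
#' @param min_area minimum component area in cells (default 5) below which a
#'   detection is treated as rasterization noise and skipped.
#' @return A one-row tibble with `bvf` (percent), `mean_radius` (um, `NA` for
#'   an empty mask), `n_detections`, and `empty` flag.
#' @export
characterize_voxel <- function(v, min_area = 5L) {
  occ <- v$occupancy
  bvf <- 100 * sum(occ) / n_cells(v$grid)
  if (bvf == 0) {
    return(tibble(
      bvf = 0, mean_radius = NA_real_, n_detections = 0L, empty = TRUE
    ))
  }
  hx <- v$grid$spacing[1]
  hy <- v$grid$spacing[2]
  diameters <- numeric(0)
  for (z in seq_len(dim(occ)[3])) {
    sl <- occ[, , z]
    if (!any(sl == 1L)) next
    cc <- EBImage::bwlabel(sl)
    ncomp <- max(cc)
    if (ncomp == 0) next
    idx <- which(cc > 0, arr.ind = TRUE)
    labs <- cc[cc > 0]
    for (k in seq_len(ncomp)) {
      sel <- labs == k
      if (sum(sel) < min_area) next
      diameters <- c(
        diameters,
        min_feret_diameter(idx[sel, 1], idx[sel, 2], hx, hy)
      )
    }
  }
  tibble(
    bvf = bvf,
    mean_radius = if (length(diameters)) mean(diameters) / 2 else NA_real_,
    n_detections = length(diameters),
    empty = FALSE
  )
}
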