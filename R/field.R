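#' Physics constants and contrast state
#'
#' Bundle of the magnetostatic and tissue constants used by the forward model.
#' `dchi_deoxy_ppm` is the susceptibility difference (SI, ppm) between fully
#' deoxygenated and fully oxygenated blood per unit haematocrit; 3.318 ppm is
#' the standard literature value (4 pi x 0.264 ppm cgs). `dchi_ca_ppm` is the
#' additional intravascular susceptibility contributed by the contrast agent
#' at steady state (0 before injection); the default is chosen to be on the
#' order of the deoxygenation contrast. Absolute SO2 estimates scale with
#' these constants, which is why they are exposed here rather than hard-coded.
#'
#' @param b0_tesla main field strength, Tesla (default 4.7).
#' @param b0_axis unit vector of the main-field direction (3D voxels).
#' @param gamma proton gyromagnetic ratio, rad/s/T.
#' @param dchi_deoxy_ppm see above.
#' @param hct haematocrit, in (0, 1).
#' @param dchi_ca_ppm intravascular susceptibility added post contrast agent.
#' @param adc water apparent diffusion coefficient, um^2/s.
#' @return A named list of class `vmrf_physics`.
#' @export
physics_constants <- function(b0_tesla = 4.7, b0_axis = c(0, 0, 1),
                              gamma = 2.67513e8, dchi_deoxy_ppm = 3.318,
                              hct = 0.42, dchi_ca_ppm = 0.5, adc = 1000) {
  b0_axis <- b0_axis / sqrt(sum(b0_axis^2))
  if (hct <= 0 || hct >= 1) abort("`hct` must be in (0, 1).")
  if (dchi_ca_ppm < 0) abort("`dchi_ca_ppm` must be >= 0.")
  structure(
    list(
      b0_tesla = b0_tesla, b0_axis = b0_axis, gamma = gamma,
      dchi_deoxy_ppm = dchi_deoxy_ppm, hct = hct,
      dchi_ca_ppm = dchi_ca_ppm, adc = adc
    ),
    class = "vmrf_physics"
  )
}

# intravascular susceptibility offset in ppm for a given oxygenation
intravascular_chi_ppm <- function(so2, physics, with_ca = FALSE) {
  physics$dchi_deoxy_ppm * physics$hct * (1 - so2 / 100) +
    if (with_ca) physics$dchi_ca_ppm else 0
}

#' Per-cell susceptibility map of a voxel
#'
#' Intravascular cells get `dchi_deoxy * hct * (1 - so2/100) + dchi_ca` ppm;
#' extravascular cells get 0. In the distributed-oxygenation mode each vessel
#' segment (by its label) is given its own SO2, which emulates an oxygen
#' gradient across the network; with every vessel set to the same value the
#' result is bit-identical to the uniform mode.
#'
#' @param v a `vmrf_voxel`.
#' @param so2 blood oxygen saturation, percent, in `[0, 100]`.
#' @param physics a [physics_constants()] bundle.
#' @param with_ca logical, add the contrast-agent susceptibility.
#' @param per_vessel_so2 optional named numeric vector or two-column data
#'   frame (`label`, `so2`) mapping every vessel label to its own SO2.
#' @return A 3D array of susceptibility offsets in ppm.
#' @export
susceptibility_map <- function(v, so2, physics = physics_constants(),
                               with_ca = FALSE, per_vessel_so2 = NULL) {
  chi <- array(0, dim(v$occupancy))
  if (is.null(per_vessel_so2)) {
    if (so2 < 0 || so2 > 100) abort("`so2` must be in [0, 100] percent.")
    chi[v$occupancy == 1L] <- intravascular_chi_ppm(so2, physics, with_ca)
  } else {
    if (is.data.frame(per_vessel_so2)) {
      map <- setNames(per_vessel_so2$so2, per_vessel_so2$label)
    } else {
      map <- per_vessel_so2
    }
    present <- sort(unique(v$labels[v$labels > 0L]))
    missing <- setdiff(as.character(present), names(map))
    if (length(missing)) {
      abort(paste0(
        "distributed-SO2 mode: no SO2 given for vessel label(s) ",
        paste(missing, collapse = ", ")
      ))
    }
    if (any(map < 0 | map > 100)) abort("per-vessel SO2 must be in [0, 100].")
    for (lb in present) {
      chi[v$labels == lb] <- intravascular_chi_ppm(
        map[[as.character(lb)]], physics, with_ca
      )
    }
  }
  chi
}

#' Magnetic field offset by the Fourier dipole-kernel method (3D)
#'
#' Solves the magnetostatic perturbation of a periodic susceptibility
#' distribution with the k-space dipole kernel `1/3 - (k . b)^2 / |k|^2`
#' along the main-field axis, and returns the offset as angular frequency
#' (rad/s) at the given field strength. The k = 0 term is set to 0: the mean
#' offset is absorbed into the rotating frame and is irrelevant to magnitude
#' signals. No Lorentz correction beyond the 1/3 term is applied.
#'
#' @param chi 3D array of susceptibility offsets in ppm.
#' @param grid the [grid_spec()] the array lives on.
#' @param physics a [physics_constants()] bundle (field strength and axis).
#' @return A `vmrf_field` object: `db` (rad/s array), `grid`, `b0`, `b0_axis`.
#' @export
field_offset <- function(chi, grid, physics = physics_constants()) {
  if (!identical(dim(chi), as.integer(grid$shape))) {
    abort("`chi` dimensions must match `grid$shape`.")
  }
  if (any(!is.finite(chi))) abort("`chi` must be finite everywhere.")
  sh <- grid$shape
  kx <- fft_freq(sh[1], grid$spacing[1])
  ky <- fft_freq(sh[2], grid$spacing[2])
  kz <- fft_freq(sh[3], grid$spacing[3])
  b <- physics$b0_axis
  kb <- outer(outer(kx * b[1], ky * b[2], "+"), kz * b[3], "+")
  k2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
  kern <- 1 / 3 - kb^2 / k2
  kern[k2 == 0] <- 0
  db_hat <- kern * fft(chi)
  db <- Re(fft(db_hat, inverse = TRUE)) / n_cells(grid)
  db <- physics$gamma * physics$b0_tesla * 1e-6 * db
  structure(
    list(db = db, grid = grid, b0 = physics$b0_tesla, b0_axis = b),
    class = "vmrf_field"
  )
}

#' Magnetic field offset for 2D disk voxels
#'
#' The 2D counterpart of [field_offset()] for the disk family: disks model the
#' cross-sections of infinite cylinders perpendicular to the simulated plane,
#' with the main field lying in the plane. The in-plane kernel is
#' `1/2 - (k . b)^2 / |k|^2` with `b` the in-plane field direction at angle
#' `b0_angle` from the +x axis. Its exterior field reproduces the closed-form
#' perpendicular-cylinder solution; the interior constant differs from the 3D
#' convention by a uniform offset, which magnitude signals cannot see.
#'
#' @param chi matrix or `nx x ny x 1` array of susceptibility offsets, ppm.
#' @param grid a 2D [grid_spec()].
#' @param physics a [physics_constants()] bundle.
#' @param b0_angle in-plane angle of the main field, radians from +x.
#' @return A `vmrf_field` object (the `db` array has `nz = 1`).
#' @export
field_offset_2d <- function(chi, grid, physics = physics_constants(),
                            b0_angle = 0) {
  if (!is_2d_grid(grid)) abort("`grid` must be 2D (nz = 1); use field_offset() for 3D.")
  if (is.matrix(chi)) dim(chi) <- c(dim(chi), 1L)
  if (!identical(dim(chi), as.integer(grid$shape))) {
    abort("`chi` dimensions must match `grid$shape`.")
  }
  sh <- grid$shape
  kx <- fft_freq(sh[1], grid$spacing[1])
  ky <- fft_freq(sh[2], grid$spacing[2])
  b <- c(cos(b0_angle), sin(b0_angle))
  kb <- outer(kx * b[1], ky * b[2], "+")
  k2 <- outer(kx^2, ky^2, "+")
  kern <- 1 / 2 - kb^2 / k2
  kern[k2 == 0] <- 0
  chi2 <- chi[, , 1]
  db <- Re(fft(kern * fft(chi2), inverse = TRUE)) / (sh[1] * sh[2])
  db <- physics$gamma * physics$b0_tesla * 1e-6 * db
  dim(db) <- sh
  structure(
    list(
      db = db, grid = grid, b0 = physics$b0_tesla,
      b0_axis = c(b, 0), b0_angle = b0_angle
    ),
    class = "vmrf_field"
  )
}

#' Field offsets of a voxel at a given contrast state
#'
#' Convenience wrapper running [susceptibility_map()] and the appropriate
#' dipole solver (2D or 3D) for one voxel. Because the field is linear in the
#' susceptibility, callers building dictionaries solve once for a unit
#' susceptibility and rescale; see [build_dictionary()].
#'
#' @inheritParams susceptibility_map
#' @param b0_angle in-plane field angle used for 2D voxels.
#' @return A `vmrf_field`.
#' @export
voxel_field <- function(v, so2, physics = physics_constants(),
                        with_ca = FALSE, per_vessel_so2 = NULL, b0_angle = 0) {
  chi <- susceptibility_map(v, so2, physics, with_ca, per_vessel_so2)
  if (is_2d_grid(v$grid)) {
    field_offset_2d(chi, v$grid, physics, b0_angle)
  } else {
    field_offset(chi, v$grid, physics)
  }
}

#' @export
print.vmrf_field <- function(x, ...) {
  cat(sprintf(
    "<vmrf_field> %d x %d x %d cells at %.2f T, db in [%.1f, %.1f] rad/s\n",
    x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], x$b0,
    min(x$db), max(x$db)
  ))
  invisible(x)
}
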