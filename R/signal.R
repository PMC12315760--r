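#' GESFIDSE sequence specification
#'
#' Gradient-Echo Sampling of the FID and Spin Echo: one spin-echo experiment
#' sampled with gradient echoes before and after the refocusing pulse. The
#' default timing is TR 4000 ms, 32 echoes, inter-echo spacing 3.3 ms and spin
#' echo at 60 ms, so echoes span 3.3-105.6 ms, the refocusing pulse sits at
#' 30 ms, and the spin echo falls between echoes 18 (59.4 ms) and 19
#' (62.7 ms). Echo placement convention: echo i occurs at `i * delta_te`.
#'
#' @param tr_ms repetition time (carried as metadata; a single excitation is
#'   simulated).
#' @param n_echoes number of gradient echoes (>= 1).
#' @param delta_te_ms inter-echo spacing, ms.
#' @param se_ms spin-echo time, ms; the ideal 180 degree pulse is applied at
#'   `se_ms / 2`, which must precede the last echo.
#' @param dt_sim_ms integration step of the isochromat solver, ms. Must
#'   divide both `delta_te_ms` and `se_ms / 2`.
#' @return A `vmrf_sequence` with the derived `echo_times_ms` and
#'   `refocus_ms`.
#' @examples
#' s <- sequence_spec()
#' range(s$echo_times_ms)
#' @export
sequence_spec <- function(tr_ms = 4000, n_echoes = 32, delta_te_ms = 3.3,
                          se_ms = 60, dt_sim_ms = 0.1) {
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 1L) abort("`n_echoes` must be >= 1.")
  if (delta_te_ms <= 0 || dt_sim_ms <= 0) abort("timings must be positive.")
  refocus_ms <- se_ms / 2
  echo_times <- seq_len(n_echoes) * delta_te_ms
  if (refocus_ms >= echo_times[n_echoes]) {
    abort("the refocusing pulse (se_ms / 2) must precede the last echo.")
  }
  divides <- function(a, b) abs(b / a - round(b / a)) < 1e-9
  if (!divides(dt_sim_ms, delta_te_ms)) {
    abort(sprintf("`dt_sim_ms` (%g) must divide `delta_te_ms` (%g).", dt_sim_ms, delta_te_ms))
  }
  if (!divides(dt_sim_ms, refocus_ms)) {
    abort(sprintf("`dt_sim_ms` (%g) must divide the refocusing time (%g ms).", dt_sim_ms, refocus_ms))
  }
  structure(
    list(
      tr_ms = tr_ms, n_echoes = n_echoes, delta_te_ms = delta_te_ms,
      se_ms = se_ms, refocus_ms = refocus_ms, dt_sim_ms = dt_sim_ms,
      echo_times_ms = echo_times
    ),
    class = "vmrf_sequence"
  )
}

#' Echo schedule of a sequence
#'
#' @param seq a [sequence_spec()].
#' @return Echo times in ms, `i * delta_te` for `i = 1..n_echoes`.
#' @export
echo_schedule <- function(seq) seq$echo_times_ms

#' @export
print.vmrf_sequence <- function(x, ...) {
  cat(sprintf(
    "<vmrf_sequence> %d echoes, dTE %g ms (%g-%g ms), SE %g ms, 180deg at %g ms, dt %g ms\n",
    x$n_echoes, x$delta_te_ms, x$echo_times_ms[1],
    x$echo_times_ms[x$n_echoes], x$se_ms, x$refocus_ms, x$dt_sim_ms
  ))
  invisible(x)
}

# Per-axis diffusion kernel taps for one time step. The per-step displacement
# sd is sigma = sqrt(2 * adc * dt). When sigma is comparable to the cell size
# the kernel is the sampled Gaussian truncated at 4 sigma; when sigma is
# smaller than the cell the sampled Gaussian is a poor quadrature, so the
# variance-matched 3-point stencil (w, 1 - 2w, w) with w = sigma^2 / (2 h^2)
# is used instead (the classical explicit diffusion stencil; over many steps
# the composed kernel tends to the correct Gaussian). Taps are normalized to
# sum exactly to 1 so a uniform magnetization is preserved to rounding.
diffusion_taps <- function(sigma_um, h_um) {
  if (sigma_um == 0) return(NULL)
  if (sigma_um < h_um) {
    w <- sigma_um^2 / (2 * h_um^2)
    taps <- c(w, 1 - 2 * w, w)
  } else {
    rad <- ceiling(4 * sigma_um / h_um)
    x <- (-rad:rad) * h_um
    taps <- exp(-x^2 / (2 * sigma_um^2))
  }
  taps / sum(taps)
}

#' Simulate the GESFIDSE magnitude response of one voxel
#'
#' Deterministic isochromat simulation on the voxel grid. The transverse
#' magnetization starts uniform; each step applies the static dephasing
#' `exp(i db dt)`, then water diffusion as a per-axis convolution of the
#' complex magnetization with a Gaussian kernel of standard deviation
#' `sqrt(2 adc dt)` (periodic wrap, matching the field solver); an ideal 180
#' degree pulse conjugates the phase at `se_ms / 2`. The recorded signal is
#' `exp(-t / T2)` times the magnitude of the spatial mean of the
#' magnetization at each echo (transverse relaxation is a uniform scalar and
#' is applied analytically, which keeps the pure-relaxation limits exact).
#' For 2D voxels dephasing and diffusion are restricted to the plane.
#'
#' @param field a `vmrf_field` from [field_offset()] / [field_offset_2d()].
#' @param t2_ms tissue transverse relaxation time, ms (> 0).
#' @param seq a [sequence_spec()].
#' @param adc water diffusion coefficient, um^2/s (>= 0; 0 gives the static
#'   dephasing regime, in which the spin echo refocuses all field-induced
#'   dephasing exactly).
#' @return A tibble with `echo_ms` and `signal` (magnitude, 1 at t = 0).
#' @examples
#' g <- grid_spec(c(16, 16, 16), 2)
#' f <- structure(list(db = array(0, g$shape), grid = g, b0 = 4.7,
#'                     b0_axis = c(0, 0, 1)), class = "vmrf_field")
#' s <- simulate_gesfidse(f, t2_ms = 60, seq = sequence_spec(dt_sim_ms = 0.3))
#' all.equal(s$signal, exp(-s$echo_ms / 60))
#' @export
simulate_gesfidse <- function(field, t2_ms, seq = sequence_spec(), adc = 1000) {
  if (!inherits(field, "vmrf_field")) abort("`field` must be a vmrf_field.")
  if (t2_ms <= 0) abort("`t2_ms` must be positive.")
  if (adc < 0) abort("`adc` must be >= 0.")
  dt <- seq$dt_sim_ms
  max_phase <- max(abs(field$db)) * dt * 1e-3
  if (max_phase >= pi / 4) {
    abort(sprintf(
      "dt_sim_ms = %g gives a per-step phase of %.3f rad (>= pi/4); use dt_sim_ms <= %.4g",
      dt, max_phase, 0.999 * (pi / 4) / (max(abs(field$db)) * 1e-3)
    ))
  }
  sigma <- sqrt(2 * adc * dt * 1e-3) # um
  grid <- field$grid
  taps <- list(
    diffusion_taps(sigma, grid$spacing[1]),
    diffusion_taps(sigma, grid$spacing[2]),
    if (is_2d_grid(grid)) NULL else diffusion_taps(sigma, grid$spacing[3])
  )
  echo_steps <- as.integer(round(seq$echo_times_ms / dt))
  refocus_step <- as.integer(round(seq$refocus_ms / dt))
  n_steps <- echo_steps[length(echo_steps)]
  mag <- .sim_gesfidse_core(
    as.numeric(field$db), grid$shape, dt, n_steps, echo_steps, refocus_step,
    taps
  )
  tibble(
    echo_ms = seq$echo_times_ms,
    signal = mag * exp(-seq$echo_times_ms / t2_ms)
  )
}

#' Assemble a pre/post-contrast fingerprint
#'
#' Concatenates the pre- and post-contrast echo magnitudes and jointly
#' L2-normalizes them, mirroring the concatenation of the two acquisitions
#' into a single fingerprint per voxel. The normalization makes the
#' fingerprint scale-invariant (dictionary matching uses dot products).
#'
#' @param pre,post numeric vectors of equal length (echo magnitudes).
#' @param meta optional list of provenance carried on the object.
#' @return A `vmrf_fingerprint`: `values` (unit L2 norm), `norm` (the factor
#'   removed), `n_echoes`, `meta`.
#' @export
make_fingerprint <- function(pre, post, meta = list()) {
  if (is.data.frame(pre)) pre <- pre$signal
  if (is.data.frame(post)) post <- post$signal
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must have the same number of echoes.")
  }
  v <- c(pre, post)
  if (any(!is.finite(v))) abort("fingerprint samples must be finite.")
  if (any(v < 0)) abort("fingerprint samples are magnitudes and must be >= 0.")
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) abort("cannot normalize an all-zero fingerprint.")
  structure(
    list(values = v / nrm, norm = nrm, n_echoes = length(pre), meta = meta),
    class = "vmrf_fingerprint"
  )
}

#' @export
print.vmrf_fingerprint <- function(x, ...) {
  cat(sprintf(
    "<vmrf_fingerprint> 2 x %d echoes, norm %.4g\n", x$n_echoes, x$norm
  ))
  invisible(x)
}

#' Forward-simulate the pre/post-contrast fingerprint of one voxel
#'
#' Runs the full forward chain for a single voxel: one unit-susceptibility
#' dipole solve (the field is linear in susceptibility, so the pre- and
#' post-contrast fields are rescalings of it), two GESFIDSE simulations, and
#' the concatenated, normalized fingerprint.
#'
#' @param v a `vmrf_voxel`.
#' @param so2 blood oxygen saturation, percent.
#' @param t2_ms tissue T2, ms.
#' @param seq a [sequence_spec()].
#' @param physics a [physics_constants()] bundle.
#' @param b0_angle in-plane field angle for 2D voxels.
#' @return A `vmrf_fingerprint` whose `meta` records the voxel's bvf and
#'   mean radius and the sampled (so2, t2).
#' @export
simulate_fingerprint <- function(v, so2, t2_ms, seq = sequence_spec(),
                                 physics = physics_constants(), b0_angle = 0) {
  unit_chi <- array(as.numeric(v$occupancy), dim(v$occupancy))
  unit_field <- if (is_2d_grid(v$grid)) {
    field_offset_2d(unit_chi, v$grid, physics, b0_angle)
  } else {
    field_offset(unit_chi, v$grid, physics)
  }
  chi_pre <- intravascular_chi_ppm(so2, physics, with_ca = FALSE)
  chi_post <- intravascular_chi_ppm(so2, physics, with_ca = TRUE)
  f_pre <- unit_field
  f_pre$db <- unit_field$db * chi_pre
  f_post <- unit_field
  f_post$db <- unit_field$db * chi_post
  pre <- simulate_gesfidse(f_pre, t2_ms, seq, physics$adc)
  post <- simulate_gesfidse(f_post, t2_ms, seq, physics$adc)
  make_fingerprint(pre, post, meta = list(
    bvf = v$bvf, radius = v$mean_radius, so2 = so2, t2 = t2_ms,
    provenance = v$provenance
  ))
}
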