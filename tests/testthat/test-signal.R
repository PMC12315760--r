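test_that("echo schedule follows i * delta_te with the documented defaults", {
  s <- sequence_spec()
  expect_length(s$echo_times_ms, 32)
  expect_equal(max(s$echo_times_ms), 105.6)
  expect_equal(s$echo_times_ms[1], 3.3)
  expect_equal(s$refocus_ms, 30)
  # the spin echo at 60 ms falls between echoes 18 and 19
  expect_equal(s$echo_times_ms[18], 59.4)
  expect_equal(s$echo_times_ms[19], 62.7)
  expect_equal(echo_schedule(sequence_spec(n_echoes = 1, delta_te_ms = 60,
    se_ms = 60, dt_sim_ms = 0.3)), 60)
  expect_true(all(diff(echo_schedule(sequence_spec())) > 0))
  # invalid timings are refused
  expect_error(sequence_spec(dt_sim_ms = 0.7), "divide")
  expect_error(sequence_spec(n_echoes = 4, delta_te_ms = 10, se_ms = 100), "precede")
})

test_that("zero field gives pure T2 decay, with and without diffusion", {
  g <- grid_spec(c(16, 16, 16), 2)
  f <- structure(
    list(db = array(0, g$shape), grid = g, b0 = 4.7, b0_axis = c(0, 0, 1)),
    class = "vmrf_field"
  )
  for (adc in c(0, 1000)) {
    s <- simulate_gesfidse(f, t2_ms = 72, seq = fast_seq(), adc = adc)
    expect_equal(s$signal, exp(-s$echo_ms / 72), tolerance = 1e-12)
  }
})

test_that("with no diffusion the spin echo refocuses static dephasing exactly", {
  g <- grid_spec(c(24, 24, 32), 2.5)
  v <- feasible_cylinder_voxel(g, radius_law_ln(4), 5, seed = 21)
  f <- voxel_field(v, so2 = 40, with_ca = TRUE)
  sq <- sequence_spec(n_echoes = 1, delta_te_ms = 60, se_ms = 60, dt_sim_ms = 0.3)
  s <- simulate_gesfidse(f, t2_ms = 55, seq = sq, adc = 0)
  expect_lt(abs(s$signal / exp(-60 / 55) - 1), 1e-9)
})

test_that("static-dephasing FID matches the closed-form phase average", {
  # with ADC = 0 the FID attenuation is exactly |< exp(i db t) >|, which can
  # be evaluated in closed form from the field histogram, independently of
  # the time-stepping solver
  g <- grid_spec(c(24, 24, 32), 2.5)
  v <- feasible_cylinder_voxel(g, radius_law_ln(5), 3, seed = 33)
  f <- voxel_field(v, so2 = 50, with_ca = TRUE)
  sq <- fast_seq()
  t2 <- 60
  s <- simulate_gesfidse(f, t2_ms = t2, seq = sq, adc = 0)
  fid <- s$echo_ms < sq$refocus_ms
  oracle <- vapply(seq_along(s$echo_ms), function(i) {
    t_s <- s$echo_ms[i] * 1e-3
    exp(-s$echo_ms[i] / t2) * Mod(mean(exp(1i * f$db * t_s)))
  }, numeric(1))[fid]
  expect_equal(s$signal[fid], oracle, tolerance = 1e-9)
})

test_that("dephasing only attenuates and more susceptibility attenuates more", {
  g <- grid_spec(c(24, 24, 32), 2.5)
  v <- feasible_cylinder_voxel(g, radius_law_ln(3.5), 6, seed = 13)
  f_pre <- voxel_field(v, so2 = 60, with_ca = FALSE)
  f_post <- voxel_field(v, so2 = 60, with_ca = TRUE)
  sq <- fast_seq()
  s_pre <- simulate_gesfidse(f_pre, 60, sq, 1000)
  s_post <- simulate_gesfidse(f_post, 60, sq, 1000)
  expect_true(all(s_pre$signal <= exp(-s_pre$echo_ms / 60) + 1e-12))
  expect_true(all(s_post$signal <= exp(-s_post$echo_ms / 60) + 1e-12))
  late <- s_pre$echo_ms > 30
  expect_true(all(s_post$signal[late] < s_pre$signal[late]))
})

test_that("the solver refuses a step size that rotates too far", {
  g <- grid_spec(c(8, 8, 8), 2)
  f <- structure(
    list(db = array(5000, g$shape) * c(1, -1), grid = g, b0 = 4.7,
      b0_axis = c(0, 0, 1)),
    class = "vmrf_field"
  )
  f$db <- array(rep(c(5000, -5000), length.out = prod(g$shape)), g$shape)
  expect_error(
    simulate_gesfidse(f, 60, sequence_spec(dt_sim_ms = 0.3), 0),
    "dt_sim_ms"
  )
})

test_that("signals are bitwise deterministic and refine stably with the grid", {
  # same continuous cylinder rasterized at 5 um and 2.5 um
  mk <- function(n, h) {
    g <- grid_spec(c(n, n, n), h)
    occ <- cylinder_mask_oracle(g, c(n * h / 2, n * h / 2, 0), c(0, 0, 1), 8)
    v <- voxel_geometry(occ, g, characterize = FALSE)
    voxel_field(v, so2 = 50, with_ca = TRUE)
  }
  sq <- fast_seq()
  s_coarse <- simulate_gesfidse(mk(24, 5), 60, sq, 1000)
  s_fine <- simulate_gesfidse(mk(48, 2.5), 60, sq, 1000)
  expect_lt(max(abs(s_fine$signal - s_coarse$signal) / s_fine$signal), 0.02)

  s_again <- simulate_gesfidse(mk(24, 5), 60, sq, 1000)
  expect_identical(s_coarse$signal, s_again$signal)
})

test_that("fingerprints concatenate, normalize, and absorb scale", {
  pre <- exp(-(1:32) / 20)
  post <- exp(-(1:32) / 12)
  fp <- make_fingerprint(pre, post)
  expect_equal(sum(fp$values^2), 1)
  expect_length(fp$values, 64)
  fp_same <- make_fingerprint(pre, pre)
  expect_equal(fp_same$values[1:32], fp_same$values[33:64])
  fp_scaled <- make_fingerprint(7 * pre, 7 * post)
  expect_equal(fp_scaled$values, fp$values)
  expect_equal(fp_scaled$norm, 7 * fp$norm)
  expect_error(make_fingerprint(pre, post[-1]), "same number")
  expect_error(make_fingerprint(pre - 1, post), ">= 0")
})
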