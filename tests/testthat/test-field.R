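test_that("susceptibility maps follow the oxygenation formula", {
  g <- small_grid_3d()
  v <- feasible_cylinder_voxel(g, radius_law_ln(3), 4, seed = 3)
  phy <- physics_constants()

  # fully oxygenated, no contrast agent: no susceptibility difference
  expect_true(all(susceptibility_map(v, 100, phy, with_ca = FALSE) == 0))

  # lower bound of the sampled range
  chi <- susceptibility_map(v, 35, phy)
  expect_equal(
    unique(chi[v$occupancy == 1L]),
    phy$dchi_deoxy_ppm * phy$hct * 0.65
  )
  expect_true(all(chi[v$occupancy == 0L] == 0))

  # contrast agent adds on top
  chi_ca <- susceptibility_map(v, 35, phy, with_ca = TRUE)
  expect_equal(
    unique(chi_ca[v$occupancy == 1L] - chi[v$occupancy == 1L]),
    phy$dchi_ca_ppm
  )
})

test_that("distributed per-vessel SO2 equals uniform mode when constant", {
  g <- small_grid_3d()
  v <- feasible_cylinder_voxel(g, radius_law_ln(3), 3, seed = 11)
  labs <- sort(unique(v$labels[v$labels > 0]))
  per <- setNames(rep(60, length(labs)), labs)
  expect_identical(
    susceptibility_map(v, 60, per_vessel_so2 = per),
    susceptibility_map(v, 60)
  )
  # heterogeneous oxygenation changes intravascular values per segment
  if (length(labs) >= 2) {
    per2 <- setNames(seq(40, 80, length.out = length(labs)), labs)
    chi2 <- susceptibility_map(v, 60, per_vessel_so2 = per2)
    expect_gt(length(unique(chi2[v$occupancy == 1L])), 1L)
  }
  # a missing label is an explicit failure
  expect_error(
    susceptibility_map(v, 60, per_vessel_so2 = per[-1]),
    "no SO2 given"
  )
})

test_that("dipole solver is linear, scales with B0, and kills uniform chi", {
  g <- grid_spec(c(16, 16, 16), 2)
  phy <- physics_constants()
  set.seed(4)
  chi1 <- array(rnorm(prod(g$shape)), g$shape)
  chi2 <- array(rnorm(prod(g$shape)), g$shape)
  f1 <- field_offset(chi1, g, phy)$db
  f2 <- field_offset(chi2, g, phy)$db
  f12 <- field_offset(2 * chi1 - 3 * chi2, g, phy)$db
  expect_equal(f12, 2 * f1 - 3 * f2, tolerance = 1e-12)

  phy2 <- physics_constants(b0_tesla = 9.4)
  expect_equal(field_offset(chi1, g, phy2)$db, 2 * f1, tolerance = 1e-12)

  # uniform chi has no spatial variation (k = 0 term is dropped)
  fu <- field_offset(array(0.7, g$shape), g, phy)$db
  expect_lt(max(abs(fu)), 1e-9)
})

test_that("rotating geometry and field axis together leaves the field alone", {
  g <- grid_spec(c(24, 24, 24), 2)
  phy_z <- physics_constants(b0_axis = c(0, 0, 1))
  phy_x <- physics_constants(b0_axis = c(1, 0, 0))
  set.seed(9)
  chi <- array(rnorm(prod(g$shape)), g$shape)
  f_z <- field_offset(chi, g, phy_z)$db
  f_x <- field_offset(aperm(chi, c(3, 2, 1)), g, phy_x)$db
  expect_equal(aperm(f_x, c(3, 2, 1)), f_z, tolerance = 1e-10)
})

test_that("2D solver matches the perpendicular-cylinder closed form", {
  n <- 128
  h <- 2
  g <- grid_spec(c(n, n, 1), h)
  phy <- physics_constants()
  r <- 8
  c0 <- n * h / 2
  chi <- array(circle_fraction(n, h, c0, r), c(n, n, 1))
  # B0 in-plane along +x
  f <- field_offset_2d(chi, g, phy, b0_angle = 0)$db[, , 1]
  gB0 <- phy$gamma * phy$b0_tesla * 1e-6
  cc <- (seq_len(n) - 0.5) * h
  dx <- matrix(cc - c0, n, n)
  dy <- matrix(cc - c0, n, n, byrow = TRUE)
  rho <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) # angle from the B0 (x) axis
  closed <- (gB0 / 2) * (r / rho)^2 * cos(2 * ang)
  sel <- rho >= 2 * r & rho <= 4 * r & abs(cos(2 * ang)) >= 0.5
  rel <- abs(f[sel] - closed[sel]) / abs(closed[sel])
  expect_lt(max(rel), 0.05)

  # uniform chi: constant offset only
  fu <- field_offset_2d(array(1, c(n, n, 1)), g, phy)$db
  expect_lt(max(abs(fu)), 1e-9)

  # 3D input is refused
  expect_error(
    field_offset_2d(array(0, c(4, 4, 4)), grid_spec(c(4, 4, 4), 2), phy),
    "2D"
  )
})
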