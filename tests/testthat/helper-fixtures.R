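# Shared small fixtures and independent oracles, built in code.

small_grid_3d <- function() grid_spec(c(24, 24, 32), 2.5)
small_grid_2d <- function() grid_spec(c(48, 48, 1), 2.5)

fast_seq <- function(...) sequence_spec(dt_sim_ms = 0.3, ...)

# lognormal radius law around `r` um (the dictionary generators' default)
radius_law_ln <- function(r, sdlog = 0.3) {
  function(k) rlnorm(k, log(r), sdlog)
}

# cylinder voxel that retries derived seeds when a (BVf, R) pair is
# geometrically infeasible at the small test-grid volumes
feasible_cylinder_voxel <- function(grid, radius_law, target_bvf, seed,
                                    attempts = 40L) {
  for (s in seed + seq_len(attempts) - 1L) {
    v <- tryCatch(
      make_cylinder_voxel(grid, radius_law, target_bvf, seed = s),
      error = function(e) e
    )
    if (!inherits(v, "error")) return(v)
  }
  stop("no feasible cylinder realization for these test parameters")
}

# a tiny cylinder dictionary on a small grid, memoised per session
.fixture_cache <- new.env(parent = emptyenv())

tiny_dictionary <- function() {
  if (is.null(.fixture_cache$tiny_dict)) {
    .fixture_cache$tiny_dict <- make_dictionary(
      n = 24, family = "cylinders", grid = small_grid_3d(),
      radius_range = c(2, 6), seq = fast_seq(), seed = 101
    )
  }
  .fixture_cache$tiny_dict
}

# independent brute-force nearest-neighbour matcher (oracle for dbm_match)
brute_force_match <- function(q, signals) {
  q <- q / sqrt(sum(q^2))
  best <- 1L
  best_score <- -Inf
  for (i in seq_len(nrow(signals))) {
    s <- sum(signals[i, ] * q)
    if (s > best_score) {
      best_score <- s
      best <- i
    }
  }
  list(row = best, score = best_score)
}

# occupancy of an infinite cylinder through a periodic box, computed directly
# (independent of the package's rasterizer)
cylinder_mask_oracle <- function(grid, p0, u, r) {
  sh <- grid$shape
  sp <- grid$spacing
  cx <- (seq_len(sh[1]) - 0.5) * sp[1]
  cy <- (seq_len(sh[2]) - 0.5) * sp[2]
  cz <- (seq_len(sh[3]) - 0.5) * sp[3]
  L <- grid$extent
  u <- u / sqrt(sum(u^2))
  wrap <- function(w, l) w - l * round(w / l)
  occ <- array(0L, sh)
  for (k in seq_len(sh[3])) {
    wx <- wrap(outer(cx - p0[1], rep(1, sh[2])), L[1])
    wy <- wrap(outer(rep(1, sh[1]), cy - p0[2]), L[2])
    wz <- wrap(cz[k] - p0[3], L[3])
    t <- wx * u[1] + wy * u[2] + wz * u[3]
    d2 <- wx^2 + wy^2 + wz^2 - t^2
    occ[, , k] <- (d2 <= r^2) * 1L
  }
  occ
}

# partial-volume (sub-sampled) cross-section mask of a circle, for field
# oracle tests where rasterization error must not mask solver error
circle_fraction <- function(n, h, c0, r, sub = 4) {
  cc <- (seq_len(n) - 0.5) * h
  frac <- matrix(0, n, n)
  off <- ((seq_len(sub) - 0.5) / sub - 0.5) * h
  for (oa in off) {
    for (ob in off) {
      frac <- frac + (outer((cc + oa - c0)^2, rep(1, n)) +
        outer(rep(1, n), (cc + ob - c0)^2) <= r^2)
    }
  }
  frac / sub^2
}
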