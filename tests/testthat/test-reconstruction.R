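test_that("dbm matches itself perfectly and equals the brute-force oracle", {
  d <- tiny_dictionary()
  n <- nrow(d$params)

  self <- dbm_match(d$signals, d)
  expect_identical(self$match_row, seq_len(n))
  expect_equal(self$score, rep(1, n), tolerance = 1e-12)

  # brute-force loop oracle on noisy queries
  noisy <- vascmrf:::with_seed(5, d$signals + matrix(rnorm(length(d$signals), 0, 0.01), n))
  got <- dbm_match(noisy, d)
  for (i in seq_len(n)) {
    bf <- brute_force_match(noisy[i, ], d$signals)
    expect_identical(got$match_row[i], bf$row)
    expect_equal(got$score[i], bf$score, tolerance = 1e-12)
  }

  # ties break to the lowest row index
  dd <- d
  dd$signals <- rbind(d$signals[1, ], d$signals)
  dd$params <- dplyr::bind_rows(d$params[1, ], d$params)
  expect_identical(dbm_match(d$signals[1, ], dd)$match_row, 1L)

  expect_error(dbm_match(d$signals[1, 1:10], d), "length")
})

test_that("clipping enforces physical ranges with flags and is idempotent", {
  e <- tibble::tibble(bvf = 101, radius = -3, so2 = 105, t2 = 500)
  c1 <- clip_estimates(e)
  expect_equal(c1$bvf, 100)
  expect_equal(c1$radius, 0)
  expect_equal(c1$so2, 100)
  expect_equal(c1$t2, 500) # T2 has no upper clip
  expect_true(c1$clipped_bvf && c1$clipped_radius && c1$clipped_so2)
  expect_false(c1$clipped_t2)
  expect_identical(clip_estimates(c1), c1)

  ok <- tibble::tibble(bvf = 3, radius = 5, so2 = 70, t2 = 60)
  c2 <- clip_estimates(ok)
  expect_equal(c2$bvf, 3)
  expect_false(any(c2$clipped_bvf, c2$clipped_radius, c2$clipped_so2, c2$clipped_t2))

  expect_error(clip_estimates(tibble::tibble(bvf = NaN, radius = 1, so2 = 1, t2 = 1)), "finite")
})

test_that("dbl recovers a known affine map and EM increases the likelihood", {
  # synthetic dictionary from a known affine params -> signals map
  set.seed(77)
  n <- 300
  L <- 4
  D <- 16
  Tmat <- cbind(
    runif(n, 1, 10), runif(n, 2, 10), runif(n, 35, 90), runif(n, 45, 110)
  )
  A <- matrix(rnorm(D * L, 0, 0.3), D, L)
  b <- rnorm(D, 5, 1)
  Y <- Tmat %*% t(A) + matrix(b, n, D, byrow = TRUE) +
    matrix(rnorm(n * D, 0, 0.01), n, D)
  d <- structure(
    list(
      params = tibble::tibble(
        voxel_id = 1:n, bvf = Tmat[, 1], radius = Tmat[, 2],
        so2 = Tmat[, 3], t2 = Tmat[, 4]
      ),
      signals = Y, norms = rep(1, n),
      meta = list(family = "affine-test", seed = 77)
    ),
    class = "vmrf_dictionary"
  )
  m <- dbl_train(d, n_components = 1, seed = 1)
  expect_true(all(diff(m$loglik) > -1e-6 * abs(m$loglik[-1])))

  # held-out points from the same map
  n2 <- 100
  T2m <- cbind(
    runif(n2, 1, 10), runif(n2, 2, 10), runif(n2, 35, 90), runif(n2, 45, 110)
  )
  Y2 <- T2m %*% t(A) + matrix(b, n2, D, byrow = TRUE)
  pred <- dbl_predict(m, Y2)
  for (j in seq_len(4)) {
    p <- as.matrix(pred[, c("bvf", "radius", "so2", "t2")])[, j]
    r2 <- 1 - sum((p - T2m[, j])^2) / sum((T2m[, j] - mean(T2m[, j]))^2)
    expect_gt(r2, 0.99)
  }
})

test_that("dbl training is seed-deterministic and predicts off the grid", {
  d <- tiny_dictionary()
  m1 <- dbl_train(d, n_components = 2, seed = 5)
  m2 <- dbl_train(d, n_components = 2, seed = 5)
  expect_identical(m1$A, m2$A)
  expect_identical(m1$loglik, m2$loglik)

  # EM likelihood is monotone on real data too
  expect_true(all(diff(m1$loglik) > -1e-6 * abs(m1$loglik[-1])))

  # noisy queries: posterior means need not coincide with grid values
  q <- vascmrf:::with_seed(3, d$signals[3, ] + rnorm(64, 0, 0.005))
  pred <- dbl_predict(m1, q)
  expect_false(any(pred$bvf %in% d$params$bvf))
  expect_true(all(pred$sd_bvf > 0))

  # the posterior mean respects the clipping contract
  expect_true(all(pred$so2 >= 0 & pred$so2 <= 100))

  expect_error(dbl_train(d, n_components = 10), "10 x n_components")
})

test_that("reconstruct_maps reproduces planted dictionary voxels exactly", {
  d <- tiny_dictionary()
  rows <- matrix(1:16, 4, 4)
  series <- array(0, c(4, 4, 64))
  for (i in 1:4) for (j in 1:4) series[i, j, ] <- d$signals[rows[i, j], ]
  maps <- reconstruct_maps(series, d, method = "dbm")
  expect_equal(maps$maps$bvf, matrix(d$params$bvf[rows], 4, 4))
  expect_equal(maps$maps$so2, matrix(d$params$so2[rows], 4, 4))
  expect_equal(maps$maps$t2, matrix(d$params$t2[rows], 4, 4))

  # masked voxels carry NA, never zero
  mask <- matrix(TRUE, 4, 4)
  mask[1, ] <- FALSE
  m2 <- reconstruct_maps(series, d, method = "dbm", mask = mask)
  expect_true(all(is.na(m2$maps$bvf[1, ])))
  expect_true(all(!is.na(m2$maps$bvf[2:4, ])))

  td <- tidy(m2)
  expect_equal(nrow(td), 16)
  expect_equal(sum(td$in_mask), 12)

  expect_error(reconstruct_maps(series[, , 1:10], d, "dbm"), "length")

  # DBL route produces maps of the same shape with quality sidecar
  mdl <- dbl_train(d, n_components = 2, seed = 5)
  m3 <- reconstruct_maps(series, mdl, method = "dbl")
  expect_equal(dim(m3$maps$t2), c(4, 4))
  expect_true(all(is.finite(m3$quality)))
})
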