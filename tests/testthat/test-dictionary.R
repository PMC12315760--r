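test_that("dictionary build keeps books straight and is reproducible", {
  d <- tiny_dictionary()
  expect_s3_class(d, "vmrf_dictionary")
  expect_equal(nrow(d$params), 24)
  expect_equal(ncol(d$signals), 64)
  expect_equal(sqrt(rowSums(d$signals^2)), rep(1, 24), tolerance = 1e-12)
  expect_true(all(d$params$so2 >= 35 & d$params$so2 <= 90))
  expect_true(all(d$params$t2 >= 45 & d$params$t2 <= 110))
  expect_true(all(is.finite(d$params$bvf)))

  # order-stable: building a subset reproduces those rows bit-for-bit
  geoms <- generate_geometry_set(6, "cylinders", grid = small_grid_3d(), seed = 101)
  samples <- sobol_sample(6, seed = 1101)
  d6 <- build_dictionary(geoms, samples, fast_seq())
  d3 <- build_dictionary(geoms[4:6], samples[4:6, ], fast_seq())
  expect_identical(d6$signals[4:6, ], d3$signals)

  # sample/geometry count mismatch fails
  expect_error(build_dictionary(geoms, samples[1:3, ], fast_seq()), "one \\(so2, t2\\) sample")
})

test_that("dictionary containers round-trip losslessly and refuse corruption", {
  d <- tiny_dictionary()
  path <- tempfile(fileext = ".vdict")
  save_dictionary(d, path)
  d2 <- load_dictionary(path)
  expect_identical(d2$params, d$params)
  expect_identical(d2$signals, d$signals)
  expect_identical(d2$norms, d$norms)
  expect_identical(d2$meta$seq, d$meta$seq)
  expect_identical(d2$meta$family, "cylinders")

  expect_error(load_dictionary(tempfile()), "not found")

  junk <- tempfile(fileext = ".vdict")
  saveRDS(list(container = "something-else"), junk)
  expect_error(load_dictionary(junk), "not a vascmrf dictionary")

  corrupt <- tempfile(fileext = ".vdict")
  payload <- readRDS(path)
  payload$signals <- payload$signals[-1, ]
  saveRDS(payload, corrupt)
  expect_error(load_dictionary(corrupt), "row counts differ")

  badver <- tempfile(fileext = ".vdict")
  payload <- readRDS(path)
  payload$version <- 99L
  saveRDS(payload, badver)
  expect_error(load_dictionary(badver), "version")
})
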