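test_that("roi_compare reproduces the textbook two-sample t-test", {
  # closed-form hand calculation on 2 x 5 per-unit means
  a <- c(3.1, 2.9, 3.4, 3.0, 3.2)
  b <- c(3.9, 4.1, 3.7, 4.4, 4.0)
  df <- tibble::tibble(
    v = c(a, b), g = rep(c("contra", "tumor"), each = 5), u = rep(1:5, 2)
  )
  res <- roi_compare(df, "v", "g", "u")
  sp2 <- (4 * stats::var(a) + 4 * stats::var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 8)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_equal(res$df, 8)
  expect_equal(res$diff, mean(a) - mean(b))
  expect_true(res$significant)

  # Welch variant differs when variances differ
  res_w <- roi_compare(df, "v", "g", "u", var_equal = FALSE)
  expect_lt(res_w$df, 8 + 1e-9)
})

test_that("identical groups give t = 0 and shifted groups are significant", {
  df_same <- tibble::tibble(
    v = rep(c(1, 2, 3, 4), 2), g = rep(c("a", "b"), each = 4), u = rep(1:4, 2)
  )
  res <- roi_compare(df_same, "v", "g", "u")
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  df_shift <- df_same
  df_shift$v[df_shift$g == "b"] <- df_shift$v[df_shift$g == "b"] + 10
  res2 <- roi_compare(df_shift, "v", "g", "u")
  expect_lt(res2$p_value, 0.05)
  expect_true(res2$significant)
})

test_that("roi_compare averages per unit first and ignores voxel order", {
  set.seed(31)
  df <- tibble::tibble(
    v = rnorm(120, rep(c(3, 5), each = 60)),
    g = rep(c("a", "b"), each = 60),
    u = rep(rep(1:4, each = 15), 2)
  )
  res <- roi_compare(df, "v", "g", "u")
  shuffled <- df[sample(nrow(df)), ]
  res2 <- roi_compare(shuffled, "v", "g", "u")
  expect_equal(res2$t, res$t)
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res$n_a, 4)

  # fewer than 2 units per group is refused
  bad <- tibble::tibble(v = 1:4, g = c("a", "a", "b", "b"), u = c(1, 1, 1, 1))
  expect_error(roi_compare(bad, "v", "g", "u"), "at least 2 units")
})
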