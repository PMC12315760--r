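#' Region-of-interest group comparison
#'
#' Averages voxel values inside each ROI for each unit (animal or phantom),
#' then compares the two groups of per-unit means with a two-sided two-sample
#' t-test at the 0.05 threshold. The per-unit means - not the pooled voxels -
#' are the test's samples: pooling voxels across units treats correlated
#' voxels as independent and inflates significance, so it is deliberately not
#' offered as a default.
#'
#' @param data tibble of voxel values with at least a value column, a group
#'   column (two levels) and a unit column.
#' @param parameter name of the value column (string).
#' @param group name of the grouping column (string); exactly two groups.
#' @param unit name of the unit (animal / phantom) column (string).
#' @param var_equal `TRUE` (default) for the Student t-test; `FALSE` for the
#'   Welch variant.
#' @return A one-row tibble: `parameter`, the two group names and their mean
#'   of per-unit means, `diff` (effect size, group 1 minus group 2), `t`,
#'   `df`, `p_value`, `significant` (p <= 0.05), and the per-group unit
#'   counts.
#' @examples
#' df <- tibble::tibble(
#'   v = c(1, 2, 3, 4, 11, 12, 13, 14),
#'   g = rep(c("a", "b"), each = 4), u = rep(1:4, 2)
#' )
#' roi_compare(df, "v", "g", "u")
#' @export
roi_compare <- function(data, parameter, group, unit, var_equal = TRUE) {
  data <- as_tibble(data)
  for (col in c(parameter, group, unit)) {
    if (!col %in% names(data)) abort(sprintf("column `%s` not found", col))
  }
  means <- data |>
    dplyr::group_by(.g = .data[[group]], .u = .data[[unit]]) |>
    dplyr::summarise(.m = mean(.data[[parameter]], na.rm = TRUE), .groups = "drop")
  gl <- unique(means$.g)
  if (length(gl) != 2) abort("`group` must have exactly two levels.")
  a <- means$.m[means$.g == gl[1]]
  b <- means$.m[means$.g == gl[2]]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 units for the t-test.")
  }
  if (sd(c(a - mean(a), b - mean(b))) == 0) {
    # identical within-group values: t.test errors on zero variance
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(
      parameter = parameter,
      group_a = as.character(gl[1]), group_b = as.character(gl[2]),
      mean_a = mean(a), mean_b = mean(b), diff = mean(a) - mean(b),
      t = if (same) 0 else Inf * sign(mean(a) - mean(b)),
      df = length(a) + length(b) - 2,
      p_value = if (same) 1 else 0,
      significant = !same,
      n_a = length(a), n_b = length(b)
    ))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  tibble(
    parameter = parameter,
    group_a = as.character(gl[1]), group_b = as.character(gl[2]),
    mean_a = mean(a), mean_b = mean(b), diff = mean(a) - mean(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, significant = tt$p.value <= 0.05,
    n_a = length(a), n_b = length(b)
  )
}
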