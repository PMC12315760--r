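#' Simulation grid specification
#'
#' A voxel-scale simulation grid: integer cell counts along (x, y, z) and the
#' physical spacing of one cell in micrometres. 2D voxels (the disk family)
#' are represented with `shape[3] = 1`. The grid is cell-centred and periodic:
#' shapes wrap at the boundaries, matching the periodic FFT field solver.
#'
#' @param shape integer vector of length 3, cells along (x, y, z); all >= 1.
#' @param spacing numeric length 1 or 3, micrometres per cell along each axis.
#'
#' @return A `vmrf_grid` object with fields `shape`, `spacing` and the derived
#'   `extent` (physical size in micrometres).
#' @examples
#' grid_spec(c(64, 64, 96), 2)
#' grid_spec(c(128, 128, 1), 1.94) # 2D disk voxel
#' @export
grid_spec <- function(shape, spacing) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    abort("`shape` must be three integers >= 1 (use nz = 1 for 2D voxels).")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be positive micrometres (length 1 or 3).")
  }
  structure(
    list(shape = shape, spacing = spacing, extent = shape * spacing),
    class = "vmrf_grid"
  )
}

#' @export
print.vmrf_grid <- function(x, ...) {
  cat(sprintf(
    "<vmrf_grid> %d x %d x %d cells, spacing %g x %g x %g um (extent %g x %g x %g um)\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$extent[1], x$extent[2], x$extent[3]
  ))
  invisible(x)
}

is_2d_grid <- function(grid) grid$shape[3] == 1L

n_cells <- function(grid) prod(grid$shape)

# FFT frequencies (cycles per micrometre) for one axis, matching stats::fft
# ordering: 0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1 over n*h.
fft_freq <- function(n, h) {
  k <- c(0:floor(n / 2), seq_len(ceiling(n / 2) - 1) - ceiling(n / 2))
  k / (n * h)
}

# Run an expression with a private, seeded RNG stream, restoring the caller's
# RNG state afterwards. All generator determinism flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
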