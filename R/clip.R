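#' Clip parameter estimates to their physical ranges
#'
#' Estimates from the learning-based reconstruction can fall outside physical
#' ranges. BVf and SO2 are clipped to [0, 100] percent, radius to [0, 250]
#' micrometres, and T2 is clipped to 0 ms on the lower end only (no upper
#' clip). Values exceeding a limit are set to that limit and the
#' corresponding flag records which bound fired. Clipping is idempotent.
#'
#' @param e a data frame / tibble with columns `bvf`, `radius`, `so2`, `t2`.
#' @return The tibble with clipped values and logical columns `clipped_bvf`,
#'   `clipped_radius`, `clipped_so2`, `clipped_t2` (OR-ed with any existing
#'   flags, so re-clipping never clears a flag).
#' @examples
#' clip_estimates(tibble::tibble(bvf = 101, radius = -3, so2 = 50, t2 = 500))
#' @export
clip_estimates <- function(e) {
  e <- as_tibble(e)
  need <- c("bvf", "radius", "so2", "t2")
  miss <- setdiff(need, names(e))
  if (length(miss)) abort(paste0("missing estimate columns: ", paste(miss, collapse = ", ")))
  vals <- e[need]
  if (any(!is.finite(as.matrix(vals)))) abort("estimates must be finite before clipping.")
  clip1 <- function(x, lo, hi = Inf) pmin(pmax(x, lo), hi)
  flags <- list(
    clipped_bvf = e$bvf < 0 | e$bvf > 100,
    clipped_radius = e$radius < 0 | e$radius > 250,
    clipped_so2 = e$so2 < 0 | e$so2 > 100,
    clipped_t2 = e$t2 < 0
  )
  e$bvf <- clip1(e$bvf, 0, 100)
  e$radius <- clip1(e$radius, 0, 250)
  e$so2 <- clip1(e$so2, 0, 100)
  e$t2 <- clip1(e$t2, 0)
  for (f in names(flags)) {
    e[[f]] <- if (f %in% names(e) && is.logical(e[[f]])) e[[f]] | flags[[f]] else flags[[f]]
  }
  e
}
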