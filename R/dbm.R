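#' Dictionary-based matching (DBM)
#'
#' Exhaustive nearest-entry search: the dot product of the (L2-normalized)
#' query fingerprint with every dictionary entry is computed and the entry
#' with the highest value wins; ties are broken by the lowest row index.
#' Estimates therefore always lie on the dictionary grid.
#'
#' @param fp a `vmrf_fingerprint`, a numeric vector of the dictionary's
#'   fingerprint length, or a matrix with one query per row.
#' @param d a `vmrf_dictionary`.
#' @return A tibble with one row per query: the matched `bvf`, `radius`,
#'   `so2`, `t2`, the winning `score` and `match_row`.
#' @examples
#' \dontrun{
#' dbm_match(d$signals[5, ], d) # self-match returns row 5 with score 1
#' }
#' @export
dbm_match <- function(fp, d) {
  if (!inherits(d, "vmrf_dictionary")) abort("`d` must be a vmrf_dictionary.")
  q <- if (inherits(fp, "vmrf_fingerprint")) {
    matrix(fp$values, nrow = 1)
  } else if (is.matrix(fp)) {
    fp
  } else {
    matrix(as.numeric(fp), nrow = 1)
  }
  if (ncol(q) != ncol(d$signals)) {
    abort(sprintf(
      "fingerprint length %d does not match dictionary signal length %d",
      ncol(q), ncol(d$signals)
    ))
  }
  if (any(!is.finite(q))) abort("query fingerprints must be finite.")
  # normalize queries so the dot product is a cosine score
  nrm <- sqrt(rowSums(q^2))
  q <- q / nrm
  scores <- d$signals %*% t(q) # n_dict x n_query
  best <- apply(scores, 2, which.max) # first index wins ties
  out <- d$params[best, c("bvf", "radius", "so2", "t2")]
  out$score <- scores[cbind(best, seq_len(ncol(scores)))]
  out$match_row <- best
  as_tibble(out)
}
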