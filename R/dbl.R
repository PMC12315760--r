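# Dictionary-based learning: Bayesian inverse regression by a Gaussian
# locally linear mapping (GLLiM). A joint Gaussian mixture over (parameters,
# signals) is fitted by EM in the parameter -> signal direction, with an
# affine map and isotropic noise per component; the signal -> parameter
# posterior is then available analytically as a Gaussian mixture, and its
# mean/sd are the DBL estimate and its uncertainty.

log_gauss_chol <- function(X, mean, chol_cov) {
  # rows of X; chol_cov upper-triangular
  Z <- forwardsolve(t(chol_cov), t(X) - mean)
  -0.5 * (nrow(chol_cov) * log(2 * pi)) - sum(log(diag(chol_cov))) -
    0.5 * colSums(Z^2)
}

gllim_em <- function(T_s, Y, K, seed, max_iter, tol, reg = 1e-6) {
  N <- nrow(T_s)
  L <- ncol(T_s)
  D <- ncol(Y)

  # k-means initialization on the standardized joint space
  Ys <- scale(Y)
  Ys[, attr(Ys, "scaled:scale") == 0] <- 0
  km <- with_seed(seed, kmeans(cbind(T_s, Ys), centers = K, nstart = 3, iter.max = 50))
  r <- matrix(0.05 / max(K - 1, 1), N, K)
  r[cbind(seq_len(N), km$cluster)] <- if (K > 1) 0.95 else 1
  if (K == 1) r[] <- 1

  pi_k <- numeric(K)
  c_k <- matrix(0, L, K)
  Gamma <- array(0, c(L, L, K))
  A <- array(0, c(D, L, K))
  b <- matrix(0, D, K)
  sigma2 <- numeric(K)
  loglik <- numeric(0)

  for (iter in seq_len(max_iter)) {
    # ---- M-step
    for (k in seq_len(K)) {
      w <- r[, k]
      sw <- sum(w)
      if (sw < L + 1e-6) stop("EM degeneracy: empty component")
      tbar <- colSums(T_s * w) / sw
      ybar <- colSums(Y * w) / sw
      Tc <- sweep(T_s, 2, tbar)
      Yc <- sweep(Y, 2, ybar)
      Stt <- crossprod(Tc * sqrt(w)) / sw
      Syt <- crossprod(Yc, Tc * w) / sw
      G <- Stt + diag(reg, L)
      Ak <- Syt %*% solve(G)
      bk <- ybar - Ak %*% tbar
      resid <- Yc - Tc %*% t(Ak)
      s2 <- sum(w * rowSums(resid^2)) / (sw * D)
      pi_k[k] <- sw / N
      c_k[, k] <- tbar
      Gamma[, , k] <- G
      A[, , k] <- Ak
      b[, k] <- bk
      sigma2[k] <- max(s2, 1e-12)
    }
    # ---- E-step
    logr <- matrix(0, N, K)
    for (k in seq_len(K)) {
      ch <- chol(Gamma[, , k])
      lt <- log_gauss_chol(T_s, c_k[, k], ch)
      pred <- T_s %*% t(A[, , k])
      pred <- sweep(pred, 2, b[, k], "+")
      rs <- rowSums((Y - pred)^2)
      ly <- -0.5 * D * log(2 * pi * sigma2[k]) - rs / (2 * sigma2[k])
      logr[, k] <- log(pi_k[k]) + lt + ly
    }
    mx <- apply(logr, 1, max)
    lse <- mx + log(rowSums(exp(logr - mx)))
    ll <- sum(lse)
    r <- exp(logr - lse)
    loglik <- c(loglik, ll)
    if (iter > 1) {
      rel <- (ll - loglik[iter - 1]) / abs(loglik[iter - 1])
      if (is.finite(rel) && abs(rel) < tol) break
    }
  }
  list(
    pi = pi_k, c = c_k, Gamma = Gamma, A = A, b = b, sigma2 = sigma2,
    loglik = loglik, converged = length(loglik) < max_iter
  )
}

#' Train a DBL (Bayesian inverse regression) model on a dictionary
#'
#' Fits a Gaussian locally linear mapping by expectation-maximization: a
#' K-component mixture in which each component carries a Gaussian over the
#' parameter space and an affine parameter-to-signal map with isotropic
#' residual noise. The fitted forward mixture is inverted analytically, so
#' [dbl_predict()] returns the posterior mean and standard deviation of the
#' parameters given a fingerprint. Unlike dictionary matching, the posterior
#' mean interpolates between dictionary grid points.
#'
#' @param d a `vmrf_dictionary`.
#' @param n_components number of mixture components (dictionary rows must be
#'   at least 10 times this).
#' @param seed seed for the k-means initialization.
#' @param max_iter,tol EM stopping rule: relative log-likelihood increase
#'   below `tol` or `max_iter` iterations.
#' @param max_restarts restarts with a jittered seed if EM degenerates
#'   (empty component / singular covariance) before failing.
#' @return A `vmrf_dbl` model.
#' @export
dbl_train <- function(d, n_components = 50, seed = 1L, max_iter = 200,
                      tol = 1e-6, max_restarts = 3L) {
  if (!inherits(d, "vmrf_dictionary")) abort("`d` must be a vmrf_dictionary.")
  K <- as.integer(n_components)
  par_cols <- c("bvf", "radius", "so2", "t2")
  Tr <- as.matrix(d$params[par_cols])
  Y <- d$signals
  if (any(!is.finite(Tr))) {
    abort("dictionary parameter table contains non-finite values (e.g. undefined mean radius); drop or regenerate those entries before training")
  }
  if (nrow(Tr) < 10L * K) {
    abort(sprintf(
      "dictionary has %d rows; at least %d (10 x n_components) are required",
      nrow(Tr), 10L * K
    ))
  }
  center <- colMeans(Tr)
  scl <- apply(Tr, 2, sd)
  scl[scl == 0] <- 1
  T_s <- sweep(sweep(Tr, 2, center), 2, scl, "/")

  fit <- NULL
  for (attempt in 0:max_restarts) {
    fit <- tryCatch(
      gllim_em(T_s, Y, K, seed + attempt, max_iter, tol),
      error = function(e) e
    )
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    abort(paste0("DBL training failed after restarts: ", conditionMessage(fit)))
  }

  structure(
    list(
      n_components = K, par_names = par_cols,
      center = center, scale = scl,
      pi = fit$pi, c = fit$c, Gamma = fit$Gamma, A = fit$A, b = fit$b,
      sigma2 = fit$sigma2,
      loglik = fit$loglik, converged = fit$converged,
      training_meta = list(
        n_rows = nrow(Tr), dictionary_family = d$meta$family,
        dictionary_seed = d$meta$seed, seed = seed,
        max_iter = max_iter, tol = tol,
        iterations = length(fit$loglik)
      )
    ),
    class = "vmrf_dbl"
  )
}

#' @export
print.vmrf_dbl <- function(x, ...) {
  cat(sprintf(
    "<vmrf_dbl> %d components over %d parameters, trained on %d rows (%s, %d EM iterations)\n",
    x$n_components, length(x$par_names), x$training_meta$n_rows,
    if (x$converged) "converged" else "max iterations reached",
    x$training_meta$iterations
  ))
  invisible(x)
}

#' @rdname dbl_train
#' @param x a `vmrf_dbl` model.
#' @export
tidy.vmrf_dbl <- function(x, ...) {
  means <- t(x$c * x$scale + x$center)
  colnames(means) <- x$par_names
  out <- as_tibble(means)
  out$component <- seq_len(x$n_components)
  out$weight <- x$pi
  out$sigma2 <- x$sigma2
  dplyr::relocate(out, .data$component, .data$weight)
}

#' @rdname dbl_train
#' @export
glance.vmrf_dbl <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    n_rows = x$training_meta$n_rows,
    iterations = x$training_meta$iterations,
    converged = x$converged,
    loglik = x$loglik[length(x$loglik)]
  )
}

#' Predict parameters from fingerprints with a DBL model
#'
#' Evaluates the analytic inverse of the trained mixture: the posterior over
#' parameters given a fingerprint is itself a Gaussian mixture, and the
#' posterior mean is reported as the estimate with the posterior standard
#' deviation as its uncertainty. Estimates are then clipped to physical
#' ranges by [clip_estimates()].
#'
#' @param m a `vmrf_dbl` model.
#' @param fp a `vmrf_fingerprint`, numeric vector, or matrix of queries
#'   (one per row). Queries are L2-normalized like the dictionary entries.
#' @return A tibble with `bvf`, `radius`, `so2`, `t2`, their posterior
#'   standard deviations (`sd_*`), and the clipping flags.
#' @export
dbl_predict <- function(m, fp) {
  if (!inherits(m, "vmrf_dbl")) abort("`m` must be a vmrf_dbl model.")
  Q <- if (inherits(fp, "vmrf_fingerprint")) {
    matrix(fp$values, nrow = 1)
  } else if (is.matrix(fp)) {
    fp
  } else {
    matrix(as.numeric(fp), nrow = 1)
  }
  if (any(!is.finite(Q))) abort("query fingerprints must be finite.")
  D <- dim(m$A)[1]
  L <- dim(m$A)[2]
  K <- m$n_components
  if (ncol(Q) != D) {
    abort(sprintf("fingerprint length %d does not match model signal length %d", ncol(Q), D))
  }
  # queries must be preprocessed exactly like the training signals
  # (fingerprints are already L2-normalized by construction)
  M <- nrow(Q)

  lognu <- matrix(0, M, K)
  tstar <- array(0, c(M, L, K))
  sstar_diag <- matrix(0, L, K) # posterior covariance diagonals per component
  for (k in seq_len(K)) {
    Ak <- m$A[, , k]
    G <- m$Gamma[, , k]
    s2 <- m$sigma2[k]
    Ginv <- solve(G)
    Sstar <- solve(Ginv + crossprod(Ak) / s2)
    Astar <- Sstar %*% t(Ak) / s2
    bstar <- Sstar %*% (Ginv %*% m$c[, k] - t(Ak) %*% m$b[, k] / s2)
    # marginal of y under component k: N(mk, s2 I + A G A')
    mk <- as.numeric(Ak %*% m$c[, k] + m$b[, k])
    # log-determinant and quadratic form via the matrix inversion lemma
    logdetV <- D * log(s2) + determinant(G, logarithm = TRUE)$modulus -
      determinant(Sstar, logarithm = TRUE)$modulus
    Z <- sweep(Q, 2, mk)
    q1 <- rowSums(Z^2) / s2
    B <- Z %*% Ak # M x L
    q2 <- rowSums((B %*% Sstar) * B) / s2^2
    lognu[, k] <- log(m$pi[k]) - 0.5 * (D * log(2 * pi) + as.numeric(logdetV) + q1 - q2)
    tstar[, , k] <- Q %*% t(Astar) + matrix(bstar, M, L, byrow = TRUE)
    sstar_diag[, k] <- diag(Sstar)
  }
  mx <- apply(lognu, 1, max)
  nu <- exp(lognu - mx)
  nu <- nu / rowSums(nu)

  post_mean <- matrix(0, M, L)
  post_m2 <- matrix(0, M, L)
  for (k in seq_len(K)) {
    post_mean <- post_mean + nu[, k] * tstar[, , k]
    post_m2 <- post_m2 + nu[, k] *
      (tstar[, , k]^2 + matrix(sstar_diag[, k], M, L, byrow = TRUE))
  }
  post_var <- pmax(post_m2 - post_mean^2, 0)

  est <- sweep(sweep(post_mean, 2, m$scale, "*"), 2, m$center, "+")
  sds <- sweep(sqrt(post_var), 2, m$scale, "*")
  colnames(est) <- m$par_names
  colnames(sds) <- paste0("sd_", m$par_names)
  clip_estimates(dplyr::bind_cols(as_tibble(est), as_tibble(sds)))
}
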