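# Multinomial sparse group lasso. One group per gene: the gene's coefficients
# across the K classes. Objective: multinomial negative log-likelihood / n +
# lambda * ( alpha * sum|beta| + (1 - alpha) * sqrt(K) * sum_g ||beta_g||_2 ),
# solved by an accelerated proximal (FISTA) block scheme in C++.

class_indicator <- function(y) {
  y <- as.factor(y)
  Y <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

#' Fit a multinomial sparse group lasso at one penalty value
#'
#' @param X samples-by-features numeric matrix (standardize beforehand).
#' @param y class labels (factor or coercible).
#' @param lambda penalty strength.
#' @param alpha mixing between elementwise L1 (`alpha`) and groupwise L2
#'   (`1 - alpha`); default 0.95.
#' @param init optional warm start: list with `B` (p x K) and `b0` (length K).
#' @param max_iter proximal iteration cap (default 1e4).
#' @param tol convergence tolerance on the max parameter change (default 1e-6).
#' @return List: `B` (p x K coefficients), `b0`, `n_iter`, `objective`,
#'   `selected` (logical per feature: group norm > 1e-8).
#' @export
sgl_fit <- function(X, y, lambda, alpha = 0.95, init = NULL,
                    max_iter = 10000L, tol = 1e-6) {
  Y <- class_indicator(y)
  K <- ncol(Y); p <- ncol(X)
  if (is.null(init)) {
    B0 <- matrix(0, p, K)
    b00 <- log(pmax(colMeans(Y), 1e-8))
    b00 <- b00 - mean(b00)
  } else {
    B0 <- init$B; b00 <- init$b0
  }
  fit <- cpp_sgl_fit(X, Y, lambda, alpha, B0, matrix(b00, 1), max_iter, tol)
  if (!fit$converged) {
    stop(sprintf(paste0("convergence error: sparse-group-lasso proximal loop did not reach ",
                        "tol=%g in %d iterations (lambda=%.4g, objective=%.6g)"),
                 tol, max_iter, lambda, fit$objective), call. = FALSE)
  }
  rownames(fit$B) <- colnames(X)
  colnames(fit$B) <- colnames(Y)
  b0 <- as.vector(fit$b0); names(b0) <- colnames(Y)
  list(B = fit$B, b0 = b0, n_iter = fit$n_iter, objective = fit$objective,
       loss = fit$loss, selected = sqrt(rowSums(fit$B^2)) > 1e-8)
}

# smallest lambda at which every group is zero (per-group bisection on the
# sparse-group subgradient condition at beta = 0)
sgl_lambda_max <- function(X, y, alpha) {
  Y <- class_indicator(y)
  K <- ncol(Y); n <- nrow(X)
  pr <- colMeans(Y)
  P0 <- matrix(pr, n, K, byrow = TRUE)
  G <- crossprod(X, P0 - Y) / n
  per_group <- vapply(seq_len(ncol(X)), function(g) {
    v <- G[g, ]
    if (alpha >= 1) return(max(abs(v)))
    zero_at <- function(l) {
      u <- sign(v) * pmax(abs(v) - l * alpha, 0)
      sqrt(sum(u^2)) <= l * (1 - alpha) * sqrt(K)
    }
    hi <- max(abs(v)) / max((1 - alpha) * sqrt(K) / sqrt(K), 1e-8) + 1e-8
    lo <- 0
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (zero_at(mid)) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  max(per_group)
}

#' Fit a sparse-group-lasso path with warm starts
#'
#' @inheritParams sgl_fit
#' @param n_lambda grid length (default 15).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @return List: `lambda` grid and `fits` (list of [sgl_fit()] results).
#' @export
sgl_path <- function(X, y, alpha = 0.95, n_lambda = 15L,
                     lambda_min_ratio = 1e-2, max_iter = 10000L, tol = 1e-6) {
  lmax <- sgl_lambda_max(X, y, alpha) * 1.02
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
  fits <- vector("list", n_lambda)
  init <- NULL
  for (i in seq_len(n_lambda)) {
    fits[[i]] <- sgl_fit(X, y, lambda[i], alpha, init = init,
                         max_iter = max_iter, tol = tol)
    init <- fits[[i]][c("B", "b0")]
  }
  list(lambda = lambda, fits = fits)
}

multinomial_deviance <- function(B, b0, X, y) {
  Y <- class_indicator(y)
  eta <- sweep(X %*% B, 2, -b0)
  m <- apply(eta, 1, max)
  ll <- rowSums(Y * eta) - m - log(rowSums(exp(eta - m)))
  -2 * sum(ll)
}

# k-fold CV over a lambda path; returns the lambda minimizing mean held-out
# multinomial deviance
sgl_cv_lambda <- function(X, y, alpha, folds, n_lambda, lambda_min_ratio,
                          max_iter = 10000L, tol = 1e-6) {
  lmax <- sgl_lambda_max(X, y, alpha) * 1.02
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
  fold_id <- stratified_folds(y, folds)
  dev <- matrix(NA_real_, folds, n_lambda)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < length(unique(y))) next
    init <- NULL
    for (i in seq_along(lambda)) {
      fit <- sgl_fit(X[tr, , drop = FALSE], y[tr], lambda[i], alpha,
                     init = init, max_iter = max_iter, tol = tol)
      init <- fit[c("B", "b0")]
      dev[f, i] <- multinomial_deviance(fit$B, fit$b0, X[!tr, , drop = FALSE], y[!tr])
    }
  }
  mdev <- colMeans(dev, na.rm = TRUE)
  lambda[which.min(mdev)]
}

#' Stability selection with the multinomial sparse group lasso
#'
#' Repeatedly (1) draws a stratified 80% resample of the samples, (2) chooses
#' the penalty by `folds`-fold cross-validated multinomial deviance on the
#' resample, (3) fits at that penalty and records which genes have nonzero
#' group norm. The panel is the set of genes selected in at least `freq_min`
#' of the runs.
#'
#' @param X genes-by-samples expression matrix.
#' @param y subtype label per sample.
#' @param n_runs number of resampling runs (default 1000; analyses in this
#'   package use 100).
#' @param folds CV folds per run (default 10).
#' @param alpha L1/group mixing (default 0.95).
#' @param n_lambda,lambda_min_ratio penalty grid (15 points, 2 decades).
#' @param freq_min selection-frequency threshold for the panel (default 0.5).
#' @param subsample resample fraction (default 0.8).
#' @param seed master seed.
#' @return List: `panel_genes`, `frequency` (named, in [0,1]), `n_runs`,
#'   `params`.
#' @export
msgl_stability <- function(X, y, n_runs = 1000L, folds = 10L, alpha = 0.95,
                           n_lambda = 15L, lambda_min_ratio = 1e-2,
                           freq_min = 0.5, subsample = 0.8, seed = 1L) {
  check_matrix(X, "expression")
  y <- as.factor(y)
  genes <- rownames(X)
  counts <- setNames(numeric(length(genes)), genes)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, r))
    idx <- stratified_subsample(y, subsample)
    Xr <- t(X[, idx, drop = FALSE])
    Xr <- scale(Xr)
    Xr[, attr(Xr, "scaled:scale") == 0] <- 0
    yr <- droplevels(y[idx])
    lam <- sgl_cv_lambda(Xr, yr, alpha, folds, n_lambda, lambda_min_ratio)
    fit <- sgl_fit(Xr, yr, lam, alpha)
    counts[fit$selected] <- counts[fit$selected] + 1
  }
  freq <- counts / n_runs
  list(panel_genes = genes[freq >= freq_min], frequency = freq,
       n_runs = n_runs,
       params = list(folds = folds, alpha = alpha, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio, freq_min = freq_min,
                     subsample = subsample, seed = seed))
}
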