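# Pharmacogenomic transfer: purity correction of bulk tumor expression,
# per-drug ridge regression trained on cell lines and applied to tumors, and
# subtype-specific agent nomination. Convention: LOWER predicted response =
# more sensitive (AUC-like response scale); the direction is stored in the
# returned model.

#' Regress tumor purity out of bulk expression
#'
#' Per gene, fits expression = a + b * purity and returns residual + a
#' (intercept restored), so corrected values are exactly uncorrelated with
#' purity and a second application is a no-op. With a constant purity vector
#' the slope is unidentifiable: the input is returned with a warning.
#'
#' @param expr genes-by-samples expression matrix.
#' @param purity per-sample purity in (0,1], named by sample id.
#' @return Corrected expression matrix.
#' @export
purity_correct <- function(expr, purity) {
  check_matrix(expr, "expression")
  assert_that(all(purity > 0 & purity <= 1), "purity must lie in (0,1]")
  assert_that(identical(names(purity), colnames(expr)),
              "purity must be named by the expression sample ids")
  if (var(purity) == 0) {
    warning("constant purity vector: correction skipped (unidentifiable slope)")
    return(expr)
  }
  pc <- purity - mean(purity)
  b <- (expr %*% pc) / sum(pc^2)
  expr - b %*% rbind(purity)
}

# closed-form ridge on standardized training features via SVD; returns a
# function of lambda
ridge_solver <- function(X, y) {
  # X: n x p (centered/scaled), y: response
  ybar <- mean(y)
  yc <- y - ybar
  sv <- svd(X)
  uty <- crossprod(sv$u, yc)
  function(lambda) {
    shrink <- sv$d / (sv$d^2 + lambda)
    coef <- sv$v %*% (shrink * uty)
    list(coef = as.vector(coef), intercept = ybar)
  }
}

#' Ridge-regression transfer of cell-line drug response to tumors
#'
#' Per drug: the ridge model is trained on cell-line expression (gene space
#' intersected with the tumor cohort, standardized on the training side) with
#' the penalty chosen by k-fold cross-validated mean-squared error; tumor
#' expression is mapped with the training standardization parameters and
#' scored. Training-side CV correlation is reported per drug.
#'
#' @param cell_expr genes-by-lines expression matrix.
#' @param drug_response long data.frame: line, drug, response.
#' @param tumor_expr genes-by-samples (purity-corrected) tumor expression.
#' @param folds CV folds (default 10).
#' @param lambda_grid ridge penalties (default 25 log-spaced in 1e-2..1e4).
#' @param seed RNG seed for fold assignment.
#' @param min_lines minimum cell lines per drug (default 20).
#' @return List of class `emtsub_drug_transfer`: `predictions` (drugs x
#'   samples), `per_drug` (lambda, cv_cor, n_lines), `coefficients`,
#'   `direction` ("lower = more sensitive").
#' @export
ridge_transfer <- function(cell_expr, drug_response, tumor_expr, folds = 10L,
                           lambda_grid = 10^seq(-2, 4, length.out = 25),
                           seed = 1L, min_lines = 20L) {
  check_matrix(cell_expr, "cell-line expression")
  check_matrix(tumor_expr, "tumor expression")
  assert_that(all(c("line", "drug", "response") %in% colnames(drug_response)),
              "drug_response needs line/drug/response columns")
  genes <- intersect(rownames(cell_expr), rownames(tumor_expr))
  if (length(genes) < 0.5 * nrow(cell_expr))
    stop("transfer-validity error: gene intersection below 50% of training genes",
         call. = FALSE)
  drugs <- unique(drug_response$drug)
  pred <- matrix(NA_real_, length(drugs), ncol(tumor_expr),
                 dimnames = list(drugs, colnames(tumor_expr)))
  per_drug <- data.frame(drug = drugs, lambda = NA_real_, cv_cor = NA_real_,
                         n_lines = NA_integer_, stringsAsFactors = FALSE)
  coefs <- list()
  set.seed(derive_seed(seed, "ridge_transfer"))
  for (di in seq_along(drugs)) {
    dd <- drug_response[drug_response$drug == drugs[di], ]
    dd <- dd[dd$line %in% colnames(cell_expr), ]
    if (nrow(dd) < min_lines)
      stop(sprintf("fewer than %d cell lines for drug %s", min_lines, drugs[di]),
           call. = FALSE)
    Xtr <- t(cell_expr[genes, dd$line, drop = FALSE])
    mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd); sg[sg == 0] <- 1
    Xs <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    y <- dd$response
    fold <- sample(rep_len(seq_len(folds), nrow(Xs)))
    cv_pred <- matrix(NA_real_, nrow(Xs), length(lambda_grid))
    for (f in seq_len(folds)) {
      tr <- fold != f
      solver <- ridge_solver(Xs[tr, , drop = FALSE], y[tr])
      for (li in seq_along(lambda_grid)) {
        b <- solver(lambda_grid[li])
        cv_pred[!tr, li] <- Xs[!tr, , drop = FALSE] %*% b$coef + b$intercept
      }
    }
    mse <- colMeans((cv_pred - y)^2)
    li <- which.min(mse)
    fit <- ridge_solver(Xs, y)(lambda_grid[li])
    Zt <- sweep(sweep(t(tumor_expr[genes, , drop = FALSE]), 2, mu), 2, sg, "/")
    pred[di, ] <- Zt %*% fit$coef + fit$intercept
    per_drug$lambda[di] <- lambda_grid[li]
    per_drug$cv_cor[di] <- cor(cv_pred[, li], y)
    per_drug$n_lines[di] <- nrow(dd)
    coefs[[drugs[di]]] <- setNames(fit$coef, genes)
  }
  out <- list(predictions = pred, per_drug = per_drug, coefficients = coefs,
              direction = "lower = more sensitive")
  class(out) <- "emtsub_drug_transfer"
  out
}

#' Nominate subtype-specific agents from predicted sensitivities
#'
#' Per drug, a Kruskal-Wallis test across subtypes (BH-adjusted over drugs);
#' a passing drug (q < `fdr_max`) is assigned to the subtype with the lowest
#' mean predicted response (most sensitive) provided its mean is at least
#' `effect_min` pooled-SD units below the runner-up. Per-drug predictions are
#' min-max normalized to [0,1] (0 = most sensitive sample).
#'
#' @param pred drugs-by-samples predicted response matrix.
#' @param subtype_labels subtype per sample (>= 2 subtypes, >= 5 samples each).
#' @param fdr_max BH threshold over drugs (default 0.05).
#' @param effect_min minimum best-vs-runner-up gap in pooled-SD units
#'   (default 0.5).
#' @return List of class `emtsub_drug_model`: `table` (drug, H, p, q,
#'   subtype, gap_sd, nominated), `normalized` (min-max matrix),
#'   `direction`.
#' @export
nominate_subtype_drugs <- function(pred, subtype_labels, fdr_max = 0.05,
                                   effect_min = 0.5) {
  y <- as.factor(subtype_labels)
  if (nlevels(y) < 2) stop("grouping error: need >= 2 subtypes", call. = FALSE)
  assert_that(min(table(y)) >= 5, "need >= 5 samples per subtype")
  assert_that(ncol(pred) == length(y), "one prediction per sample required")
  kw <- apply(pred, 1, function(v) {
    k <- kruskal_wallis(v, y)
    c(H = k$H, p = k$p)
  })
  q <- bh_adjust(kw["p", ])
  tab <- data.frame(drug = rownames(pred), H = kw["H", ], p = kw["p", ], q = q,
                    subtype = NA_character_, gap_sd = NA_real_,
                    nominated = FALSE, stringsAsFactors = FALSE, row.names = NULL)
  pooled_sd <- apply(pred, 1, function(v) {
    sqrt(mean(tapply(v, y, var), na.rm = TRUE))
  })
  for (i in seq_len(nrow(pred))) {
    means <- sort(tapply(pred[i, ], y, mean))
    gap <- (means[2] - means[1]) / max(pooled_sd[i], 1e-12)
    tab$gap_sd[i] <- gap
    if (q[i] < fdr_max && gap >= effect_min) {
      tab$subtype[i] <- names(means)[1]
      tab$nominated[i] <- TRUE
    }
  }
  normalized <- t(apply(pred, 1, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  }))
  dimnames(normalized) <- dimnames(pred)
  out <- list(table = tab, normalized = normalized,
              direction = "lower = more sensitive")
  class(out) <- "emtsub_drug_model"
  out
}
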