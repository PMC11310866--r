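# Stage-by-stage derivation of the gene-panel subtype classifier: consensus
# differential analysis (moderated t + SAM + maxT, one-vs-rest), logistic
# quality control, correlation de-collinearization, Boruta and SVM-RFE
# wrappers, sparse-group-lasso stability selection, and cross-validated model
# competition over five families.

# vectorized two-group statistics over the rows of X
row_two_group <- function(X, i1, i2, s0 = 0) {
  n1 <- sum(i1); n2 <- sum(i2)
  X1 <- X[, i1, drop = FALSE]; X2 <- X[, i2, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- (rowSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(X2^2) - n2 * m2^2) / (n2 - 1)
  s <- sqrt(pmax(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2), 0) *
              (1 / n1 + 1 / n2))
  list(d = (m2 - m1) / (s + s0), s = s, delta = m2 - m1)
}

# SAM fudge factor: the s0 (among quantile candidates of s) minimizing the
# coefficient of variation of the windowed median absolute deviation of d
sam_s0 <- function(delta, s, n_windows = 10L) {
  cands <- unique(quantile(s, seq(0, 1, 0.05), names = FALSE))
  qs <- quantile(s, seq(0, 1, length.out = n_windows + 1), names = FALSE)
  win <- cut(s, unique(qs), include.lowest = TRUE)
  cv <- vapply(cands, function(s0) {
    d <- delta / (s + s0)
    v <- tapply(d, win, mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  cands[which.min(cv)]
}

#' SAM differential statistic with permutation q-values
#'
#' Two-group SAM statistic d = (mean2 - mean1) / (s + s0) per gene, with the
#' fudge factor s0 chosen to minimize the coefficient of variation of the
#' windowed median absolute deviation of d across quantile windows of s.
#' Significance is assessed by label permutation: per-gene p-values against
#' the null distribution of d pooled across genes and permutations, then
#' BH-adjusted to q-values.
#'
#' @param X genes-by-samples matrix.
#' @param y two-level labels (e.g. one-vs-rest indicator).
#' @param n_perm number of label permutations (default 100).
#' @param seed RNG seed.
#' @param s0 optional fixed fudge factor (0 gives the ordinary pooled t form).
#' @return data.frame: gene, d, s, p, q; attribute `s0`.
#' @export
sam_statistic <- function(X, y, n_perm = 100L, seed = 1L, s0 = NULL) {
  check_matrix(X, "expression")
  y <- as.factor(y)
  assert_that(nlevels(y) == 2, "y must be two-level")
  assert_that(min(table(y)) >= 3, "need >= 3 samples per class")
  assert_that(n_perm >= 100, "n_perm must be >= 100")
  i1 <- y == levels(y)[1]; i2 <- !i1
  obs <- row_two_group(X, i1, i2)
  if (is.null(s0)) s0 <- sam_s0(obs$delta, obs$s)
  d <- obs$delta / (obs$s + s0)
  set.seed(seed)
  null_d <- matrix(NA_real_, nrow(X), n_perm)
  for (b in seq_len(n_perm)) {
    yp <- sample(y)
    pb <- row_two_group(X, yp == levels(y)[1], yp != levels(y)[1])
    null_d[, b] <- pb$delta / (pb$s + s0)
  }
  null_abs <- sort(abs(as.vector(null_d)))
  exceed <- length(null_abs) - findInterval(abs(d) - 1e-12, null_abs)
  p <- (1 + exceed) / (1 + length(null_abs))
  if (length(unique(p)) < 10)
    warning(sprintf("permutation resolution limited: %d distinct p-values", length(unique(p))))
  out <- data.frame(gene = rownames(X), d = d, s = obs$s, p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "s0") <- s0
  out
}

#' Westfall-Young maxT resampling adjustment
#'
#' Per gene, the ordinary two-group t statistic; per label permutation, the
#' maximum |t| over genes. Single-step adjusted p = fraction of permutations
#' whose max |t| reaches the observed |t| (with the +1 convention), enforced
#' monotone in observed significance. Raw per-gene permutation p-values are
#' also returned (always <= the adjusted ones).
#'
#' @param X genes-by-samples matrix.
#' @param y two-level labels.
#' @param n_resample number of permutations (default 100).
#' @param seed RNG seed.
#' @param perms optional explicit permutation matrix (rows = permuted sample
#'   orderings) for exhaustive small-n oracles; overrides `n_resample`.
#' @return data.frame: gene, t, raw_p, adj_p.
#' @export
maxt_adjust <- function(X, y, n_resample = 100L, seed = 1L, perms = NULL) {
  check_matrix(X, "expression")
  y <- as.factor(y)
  assert_that(nlevels(y) == 2, "y must be two-level")
  if (is.null(perms)) assert_that(n_resample >= 100, "n_resample must be >= 100")
  i1 <- y == levels(y)[1]
  tobs <- row_two_group(X, i1, !i1)$d
  set.seed(seed)
  B <- if (is.null(perms)) n_resample else nrow(perms)
  tperm <- matrix(NA_real_, nrow(X), B)
  for (b in seq_len(B)) {
    yp <- if (is.null(perms)) sample(y) else y[perms[b, ]]
    tperm[, b] <- row_two_group(X, yp == levels(y)[1], yp != levels(y)[1])$d
  }
  maxT <- apply(abs(tperm), 2, max)
  raw_p <- (1 + rowSums(abs(tperm) >= abs(tobs) - 1e-12)) / (1 + B)
  adj_p <- (1 + vapply(abs(tobs), function(t0) sum(maxT >= t0 - 1e-12), numeric(1))) / (1 + B)
  # monotone enforcement in order of decreasing |t|
  o <- order(-abs(tobs))
  adj_p[o] <- cummax(adj_p[o])
  adj_p <- pmax(adj_p, raw_p)
  data.frame(gene = rownames(X), t = tobs, raw_p = raw_p, adj_p = pmin(adj_p, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus differential analysis across three algorithms
#'
#' One-vs-rest per subtype: a gene enters the subtype's set only if it is
#' significant by ALL of the moderated t (q < `q_max`), SAM (q < `q_max`),
#' and maxT (adjusted p < `q_max`). The union over subtypes is returned, with
#' per-subtype provenance.
#'
#' @param X genes-by-samples expression matrix.
#' @param subtype_labels subtype per sample (>= 2 classes).
#' @param q_max significance threshold for all three algorithms (default 0.05).
#' @param n_perm permutations for SAM and maxT (default 100).
#' @param seed master seed.
#' @return List: `consensus_da_genes` (union), `per_subtype` (named list),
#'   `tables` (per-subtype result tables).
#' @export
consensus_da <- function(X, subtype_labels, q_max = 0.05, n_perm = 100L, seed = 1L) {
  y <- as.factor(subtype_labels)
  assert_that(nlevels(y) >= 2, "need >= 2 subtypes")
  per <- list(); tabs <- list()
  for (lev in levels(y)) {
    ovr <- factor(ifelse(y == lev, "this", "rest"), levels = c("rest", "this"))
    mt <- moderated_t(X, ovr, use_m_values = FALSE)
    sam <- sam_statistic(X, ovr, n_perm = n_perm, seed = derive_seed(seed, paste0("sam", lev)))
    mx <- maxt_adjust(X, ovr, n_resample = n_perm, seed = derive_seed(seed, paste0("maxt", lev)))
    hit <- rownames(X)[mt$q < q_max & sam$q < q_max & mx$adj_p < q_max]
    if (length(hit) == 0)
      warning(sprintf("empty consensus intersection for subtype %s", lev))
    per[[lev]] <- hit
    tabs[[lev]] <- list(moderated_t = mt, sam = sam, maxt = mx)
  }
  union_genes <- rownames(X)[rownames(X) %in% unique(unlist(per))]
  list(consensus_da_genes = union_genes, per_subtype = per, tables = tabs)
}

#' Logistic-regression quality control of candidate genes
#'
#' Per iteration, fits a univariate logistic regression (intercept + gene) for
#' each gene and each subtype (one-vs-rest) on a stratified subsample; a gene
#' scores a hit when its slope is Wald-significant (p < 0.05) for at least one
#' subtype. Genes retained in at least `retain_frac` of iterations survive
#' ("leaf genes"). Perfect separation is tamed by slope clipping (flagged).
#'
#' @param X genes-by-samples expression matrix.
#' @param subtype_labels subtype per sample.
#' @param genes candidate gene ids (subset of rownames(X)).
#' @param n_iter iterations (default 1000).
#' @param subsample stratified subsample fraction per iteration (default 0.8).
#' @param retain_frac retention-frequency threshold (default 0.5).
#' @param seed master seed.
#' @param p_cut per-gene Wald threshold (default 0.05).
#' @return List: `leaf_genes`, `frequency` (named), `n_separation_flags`.
#' @export
logistic_qc <- function(X, subtype_labels, genes, n_iter = 1000L, subsample = 0.8,
                        retain_frac = 0.5, seed = 1L, p_cut = 0.05) {
  assert_that(all(genes %in% rownames(X)), "genes must be rows of X")
  assert_that(n_iter >= 1, "n_iter must be >= 1")
  y <- as.factor(subtype_labels)
  Xg <- X[genes, , drop = FALSE]
  hits <- setNames(numeric(length(genes)), genes)
  n_flags <- 0L
  set.seed(derive_seed(seed, "logistic_qc"))
  for (it in seq_len(n_iter)) {
    idx <- if (n_iter == 1L && subsample >= 1) seq_len(ncol(Xg)) else
      stratified_subsample(y, subsample)
    sig <- rep(FALSE, length(genes))
    for (lev in levels(y)) {
      yb <- as.numeric(y[idx] == lev)
      res <- cpp_ulogit(Xg[, idx, drop = FALSE], yb, 25L)
      sig <- sig | (res[, 3] < p_cut)
      n_flags <- n_flags + sum(res[, 4])
    }
    hits[sig] <- hits[sig] + 1
  }
  freq <- hits / n_iter
  if (n_flags > 0) message(n_flags, " perfect-separation flags (slopes clipped)")
  list(leaf_genes = genes[freq >= retain_frac], frequency = freq,
       n_separation_flags = n_flags)
}

#' Greedy Pearson-correlation collinearity filter
#'
#' Genes are visited in order of decreasing median absolute deviation; a gene
#' is dropped if its absolute Pearson correlation with any already-retained
#' gene exceeds `r_max`. Deterministic.
#'
#' @param X genes-by-samples matrix.
#' @param genes candidate gene ids.
#' @param r_max correlation threshold in (0, 1] (default 0.9).
#' @return Character vector of retained genes.
#' @export
correlation_filter <- function(X, genes, r_max = 0.9) {
  assert_that(r_max > 0 && r_max <= 1, "r_max must lie in (0,1]")
  assert_that(all(genes %in% rownames(X)), "genes must be rows of X")
  thr <- min(r_max, 1 - 1e-12)
  mads <- apply(X[genes, , drop = FALSE], 1, mad)
  ord <- genes[order(-mads, genes)]
  kept <- character(0)
  for (g in ord) {
    if (length(kept) == 0) { kept <- g; next }
    r <- abs(cor(X[g, ], t(X[kept, , drop = FALSE])))
    if (all(r <= thr)) kept <- c(kept, g)
  }
  genes[genes %in% kept]
}

#' Boruta all-relevant feature selection
#'
#' Shadow-feature algorithm: each round appends an independently permuted copy
#' of every undecided gene, fits a random forest, and counts a hit when the
#' real gene's impurity importance exceeds the maximum shadow importance.
#' After each round a two-sided binomial test against p = 0.5 confirms (many
#' hits) or rejects (few hits) genes at level `alpha`; genes still tentative
#' at `max_rounds` are resolved by comparing their median importance across
#' rounds with the median of the max-shadow importances.
#'
#' @param X genes-by-samples matrix.
#' @param y class labels.
#' @param n_trees trees per forest (default 300).
#' @param max_rounds maximum rounds (default 50, must be >= 10).
#' @param alpha binomial test level (default 0.01).
#' @param seed master seed.
#' @return List: `confirmed`, `rejected`, `tentative_resolved`, `hits`,
#'   `rounds_used`.
#' @export
boruta_select <- function(X, y, n_trees = 300L, max_rounds = 50L, alpha = 0.01,
                          seed = 1L) {
  assert_that(max_rounds >= 10, "max_rounds must be >= 10")
  y <- as.factor(y)
  genes <- rownames(X)
  status <- setNames(rep("undecided", length(genes)), genes)
  hits <- setNames(integer(length(genes)), genes)
  imp_hist <- list(); shadow_hist <- numeric(0)
  r <- 0L
  set.seed(derive_seed(seed, "boruta"))
  while (r < max_rounds && any(status == "undecided")) {
    r <- r + 1L
    und <- names(status)[status == "undecided"]
    Xr <- t(X[und, , drop = FALSE])
    Xs <- apply(Xr, 2, sample)
    colnames(Xs) <- paste0("shadow_", und)
    df <- data.frame(Xr, Xs, check.names = FALSE)
    rf <- ranger::ranger(x = df, y = y, num.trees = n_trees,
                         importance = "impurity",
                         seed = derive_seed(seed, 7000L + r),
                         num.threads = 1)
    imp <- rf$variable.importance
    max_shadow <- max(imp[paste0("shadow_", und)])
    real_imp <- imp[und]
    hits[und] <- hits[und] + as.integer(real_imp > max_shadow)
    imp_hist[[r]] <- real_imp
    shadow_hist[r] <- max_shadow
    if (r >= 5) {
      for (g in und) {
        pv <- binom.test(hits[[g]], r, 0.5)$p.value
        if (pv < alpha) status[g] <- if (hits[[g]] > r / 2) "confirmed" else "rejected"
      }
    }
  }
  tent <- names(status)[status == "undecided"]
  resolved <- character(0)
  if (length(tent) > 0) {
    med_shadow <- median(shadow_hist)
    for (g in tent) {
      med_imp <- median(vapply(imp_hist, function(h) if (g %in% names(h)) h[[g]] else NA_real_,
                               numeric(1)), na.rm = TRUE)
      status[g] <- if (isTRUE(med_imp > med_shadow)) "confirmed" else "rejected"
      if (status[g] == "confirmed") resolved <- c(resolved, g)
    }
  }
  confirmed <- names(status)[status == "confirmed"]
  if (length(confirmed) == 0) warning("Boruta confirmed no features")
  list(confirmed = confirmed, rejected = names(status)[status == "rejected"],
       tentative_resolved = resolved, hits = hits, rounds_used = r)
}

#' SVM recursive feature elimination (one-vs-rest, linear kernel)
#'
#' Iteratively fits one linear SVM per class (class vs rest) on standardized
#' features, ranks genes by the sum over classes of squared weights, and
#' removes the lowest-ranked `step_frac` fraction (at least one) per round
#' until none remain. The full elimination order is returned (last eliminated
#' = most informative).
#'
#' @param X genes-by-samples matrix.
#' @param y class labels.
#' @param step_frac fraction removed per round (default 0.1).
#' @param target_size optional panel size to report as `selected`.
#' @param cost SVM cost parameter (default 1).
#' @return List: `ranking` (best gene first), `elimination_order` (first
#'   eliminated first), `selected` (top `target_size`, if given).
#' @export
svm_rfe <- function(X, y, step_frac = 0.1, target_size = NULL, cost = 1) {
  y <- as.factor(y)
  genes <- rownames(X)
  if (!is.null(target_size) && target_size > length(genes))
    stop("size error: target_size exceeds available genes", call. = FALSE)
  Z <- t(scale(t(X)))
  Z[!is.finite(Z)] <- 0
  remaining <- genes
  eliminated <- character(0)
  while (length(remaining) > 0) {
    score <- setNames(numeric(length(remaining)), remaining)
    for (lev in levels(y)) {
      yb <- factor(ifelse(y == lev, "this", "rest"), levels = c("rest", "this"))
      m <- e1071::svm(x = t(Z[remaining, , drop = FALSE]), y = yb,
                      kernel = "linear", cost = cost, scale = FALSE)
      w <- as.vector(t(m$coefs) %*% m$SV)
      score <- score + w^2
    }
    n_rm <- max(1L, floor(step_frac * length(remaining)))
    n_rm <- min(n_rm, length(remaining))
    drop_g <- names(sort(score))[seq_len(n_rm)]
    eliminated <- c(eliminated, drop_g)
    remaining <- setdiff(remaining, drop_g)
  }
  ranking <- rev(eliminated)
  out <- list(ranking = ranking, elimination_order = eliminated)
  if (!is.null(target_size)) out$selected <- ranking[seq_len(target_size)]
  out
}

#' Derive the subtype gene panel through the full selection cascade
#'
#' Runs consensus differential analysis, logistic quality control, the
#' correlation filter, the Boruta and SVM-RFE wrappers (combined by union),
#' and sparse-group-lasso stability selection, recording the surviving gene
#' list of every stage.
#'
#' @param X genes-by-samples expression matrix.
#' @param subtype_labels subtype per sample.
#' @param seed master seed.
#' @param qc_iter logistic-QC iterations (default 1000).
#' @param stability_runs stability-selection runs (default 1000; analyses in
#'   this package use 100).
#' @param svm_rfe_frac fraction of the post-filter genes kept by SVM-RFE
#'   (default 0.5).
#' @param n_perm permutations for the differential stage (default 100).
#' @param r_max correlation-filter threshold (default 0.9).
#' @param retain_frac,freq_min retention thresholds of QC and stability
#'   selection (default 0.5 each).
#' @return List of class `emtsub_panel_trace` with stage-wise gene lists,
#'   selection frequencies and per-stage parameters.
#' @export
derive_panel <- function(X, subtype_labels, seed = 1L, qc_iter = 1000L,
                         stability_runs = 1000L, svm_rfe_frac = 0.5,
                         n_perm = 100L, r_max = 0.9, retain_frac = 0.5,
                         freq_min = 0.5) {
  check_matrix(X, "expression")
  y <- as.factor(subtype_labels)
  da <- consensus_da(X, y, n_perm = n_perm, seed = derive_seed(seed, "da"))
  if (length(da$consensus_da_genes) == 0)
    stop("no genes survive consensus differential analysis", call. = FALSE)
  qc <- logistic_qc(X, y, da$consensus_da_genes, n_iter = qc_iter,
                    retain_frac = retain_frac, seed = derive_seed(seed, "qc"))
  post_cor <- correlation_filter(X, qc$leaf_genes, r_max = r_max)
  bor <- boruta_select(X[post_cor, , drop = FALSE], y,
                       seed = derive_seed(seed, "boruta"))
  rfe <- svm_rfe(X[post_cor, , drop = FALSE], y,
                 target_size = max(1L, ceiling(svm_rfe_frac * length(post_cor))))
  wrapper <- post_cor[post_cor %in% union(bor$confirmed, rfe$selected)]
  if (length(wrapper) < 2)
    stop("fewer than two genes survive the wrapper stage", call. = FALSE)
  stab <- msgl_stability(X[wrapper, , drop = FALSE], y, n_runs = stability_runs,
                         freq_min = freq_min, seed = derive_seed(seed, "msgl"))
  out <- list(consensus_da_genes = da$consensus_da_genes,
              per_subtype_da = da$per_subtype,
              leaf_genes = qc$leaf_genes,
              qc_frequency = qc$frequency,
              post_correlation_genes = post_cor,
              boruta_confirmed = bor$confirmed,
              svm_rfe_selected = rfe$selected,
              wrapper_genes = wrapper,
              panel_genes = stab$panel_genes,
              selection_frequency = stab$frequency,
              params = list(seed = seed, qc_iter = qc_iter,
                            stability_runs = stability_runs,
                            svm_rfe_frac = svm_rfe_frac, n_perm = n_perm,
                            r_max = r_max, retain_frac = retain_frac,
                            freq_min = freq_min))
  class(out) <- "emtsub_panel_trace"
  out
}
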