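# Per-sample EMT state scores. The three published signature scores are
# operationalized as: EMTKS -> a per-sample two-sample Kolmogorov-Smirnov
# comparison of epithelial vs mesenchymal signature expression; EMT76GS -> a
# correlation-weighted 76-gene sum anchored on a reference epithelial gene
# (higher = epithelial); "EMT score" -> mean(M) - mean(E) per sample. All
# three are swappable conventions, documented in the methods vignette.

map_set <- function(expr, set, min_n, what) {
  hit <- intersect(set, rownames(expr))
  if (length(hit) < min_n) {
    stop(sprintf("insufficient signature: %s maps %d gene(s) (need >= %d); missing: %s",
                 what, length(hit), min_n,
                 paste(head(setdiff(set, rownames(expr)), 10), collapse = ", ")),
         call. = FALSE)
  }
  hit
}

#' Kolmogorov-Smirnov EMT score
#'
#' Per sample, compares the empirical CDFs of the epithelial-set and
#' mesenchymal-set expression values: with D_M = max(F_E - F_M) and
#' D_E = max(F_M - F_E) over the pooled grid, the score is D_M - D_E in
#' [-1, 1]; positive = mesenchymal-shifted. Rank-based, hence invariant to
#' strictly monotone transforms of a sample's expression.
#'
#' @param expr log-expression matrix (genes x samples).
#' @param epithelial_set,mesenchymal_set character vectors of gene ids; each
#'   must map at least 3 genes into the matrix.
#' @return Named numeric vector of per-sample scores.
#' @export
score_ks <- function(expr, epithelial_set, mesenchymal_set) {
  check_matrix(expr, "expression")
  e <- map_set(expr, epithelial_set, 3, "epithelial set")
  m <- map_set(expr, mesenchymal_set, 3, "mesenchymal set")
  sc <- vapply(seq_len(ncol(expr)), function(s) {
    xe <- expr[e, s]; xm <- expr[m, s]
    grid <- sort(unique(c(xe, xm)))
    Fe <- vapply(grid, function(t) mean(xe <= t), numeric(1))
    Fm <- vapply(grid, function(t) mean(xm <= t), numeric(1))
    max(Fe - Fm) - max(Fm - Fe)
  }, numeric(1))
  names(sc) <- colnames(expr)
  sc
}

#' Correlation-weighted 76-gene EMT score
#'
#' Each signature gene is weighted by its cohort-wide Pearson correlation with
#' a reference epithelial gene (CDH1-style anchor); the score is the weighted
#' sum of the sample's signature expression. Higher = epithelial.
#'
#' @param expr log-expression matrix.
#' @param signature_genes signature gene ids (>= 10 must map).
#' @param reference_epithelial_gene anchor gene id (must be present).
#' @return Named numeric scores, with the mapped genes in attribute
#'   `mapped_genes` and weights in `weights`.
#' @export
score_76gs <- function(expr, signature_genes, reference_epithelial_gene) {
  check_matrix(expr, "expression")
  if (!reference_epithelial_gene %in% rownames(expr)) {
    stop(sprintf("reference gene '%s' absent; candidates in matrix include: %s",
                 reference_epithelial_gene,
                 paste(head(intersect(signature_genes, rownames(expr)), 5),
                       collapse = ", ")), call. = FALSE)
  }
  sig <- map_set(expr, signature_genes, 10, "76-gene signature")
  ref <- expr[reference_epithelial_gene, ]
  w <- apply(expr[sig, , drop = FALSE], 1, function(x) {
    if (sd(x) == 0 || sd(ref) == 0) 0 else cor(x, ref)
  })
  sc <- as.vector(t(expr[sig, , drop = FALSE]) %*% w)
  names(sc) <- colnames(expr)
  attr(sc, "mapped_genes") <- sig
  attr(sc, "weights") <- w
  sc
}

#' Mean-difference EMT score
#'
#' mean(mesenchymal-set expression) - mean(epithelial-set expression) per
#' sample; positive = mesenchymal-shifted.
#'
#' @inheritParams score_ks
#' @return Named numeric scores.
#' @export
score_mlr <- function(expr, epithelial_set, mesenchymal_set) {
  check_matrix(expr, "expression")
  e <- map_set(expr, epithelial_set, 1, "epithelial set")
  m <- map_set(expr, mesenchymal_set, 1, "mesenchymal set")
  sc <- colMeans(expr[m, , drop = FALSE]) - colMeans(expr[e, , drop = FALSE])
  names(sc) <- colnames(expr)
  sc
}

#' Single-sample GSEA enrichment scores
#'
#' Per sample: genes are ranked by expression (descending; ties broken by
#' stable gene order); the enrichment score of a set is the sum over the gene
#' list of the running difference between the rank^alpha-weighted in-set mass
#' and the uniform out-of-set mass. With `normalize = TRUE` all scores are
#' divided by max(ES) - min(ES) over the full matrix. Rank-based, hence
#' invariant to strictly monotone transforms of a sample's expression.
#'
#' @param expr log-expression matrix.
#' @param gene_sets named list of gene-id vectors; each set must leave at
#'   least one gene of the matrix out and map at least one in.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize scale scores by the global (max - min) (default FALSE).
#' @return Matrix of enrichment scores (sets x samples).
#' @export
ssgsea <- function(expr, gene_sets, alpha = 0.25, normalize = FALSE) {
  check_matrix(expr, "expression")
  assert_that(is.list(gene_sets) && length(names(gene_sets)) == length(gene_sets),
              "gene_sets must be a named list")
  n_genes <- nrow(expr)
  members <- lapply(gene_sets, function(s) {
    hit <- rownames(expr) %in% s
    if (!any(hit)) stop("empty set after mapping", call. = FALSE)
    if (all(hit)) stop("degenerate set: covers every gene in the matrix", call. = FALSE)
    hit
  })
  es <- matrix(0, length(gene_sets), ncol(expr),
               dimnames = list(names(gene_sets), colnames(expr)))
  for (s in seq_len(ncol(expr))) {
    # descending expression; ties resolved by original gene order
    ord <- order(-expr[, s], seq_len(n_genes))
    rank_val <- (n_genes:1)^alpha  # weight of position i in the walk
    for (j in seq_along(members)) {
      inset <- members[[j]][ord]
      w <- rank_val * inset
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset) / sum(!inset)
      es[j, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) es <- es / (max(es) - min(es))
  es
}
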