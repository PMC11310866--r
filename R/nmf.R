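#' Brunet KL-divergence NMF by multiplicative updates
#'
#' Factorizes a nonnegative gene-by-sample matrix V ~ W %*% H by minimizing
#' the generalized Kullback-Leibler divergence D(V || WH) with Brunet's
#' multiplicative updates. W and H are initialized i.i.d. uniform(0, mean(V)),
#' which makes the sample connectivity (argmax over the rows of H per column)
#' equivariant to rescaling of V. Iteration stops when the connectivity is
#' unchanged for `conn_stop` consecutive checks (every `check_every`
#' iterations) or at `max_iter`. Update denominators are floored at 1e-12.
#'
#' @param V nonnegative numeric matrix, no all-zero rows or columns.
#' @param k factorization rank, < min(dim(V)).
#' @param seed integer seed for the initialization.
#' @param max_iter iteration cap (default 2000).
#' @param conn_stop consecutive unchanged connectivity checks required to
#'   declare convergence (default 40).
#' @param check_every connectivity check interval in iterations (default 10).
#' @param kl_every record the KL divergence every this many iterations
#'   (default 1; the final value is always recorded).
#' @return List of class `emtsub_nmf`: `W`, `H`, `kl_trace`, `n_iter`,
#'   `seed`, `conn_converged`.
#' @export
nmf_brunet <- function(V, k, seed = 1L, max_iter = 2000L, conn_stop = 40L,
                       check_every = 10L, kl_every = 1L) {
  assert_that(is.matrix(V) && is.numeric(V), "V must be a numeric matrix")
  if (any(V < 0)) stop("domain error: V has negative entries", call. = FALSE)
  if (any(rowSums(V) == 0) || any(colSums(V) == 0))
    stop("domain error: V has all-zero rows or columns", call. = FALSE)
  if (k >= min(dim(V))) stop("rank error: k must be < min(dim(V))", call. = FALSE)
  set.seed(seed)
  a <- mean(V)
  W <- matrix(runif(nrow(V) * k, 0, a), nrow(V), k)
  H <- matrix(runif(k * ncol(V), 0, a), k, ncol(V))
  fit <- cpp_nmf_brunet(V, W, H, as.integer(max_iter), as.integer(check_every),
                        as.integer(conn_stop), as.integer(kl_every))
  rownames(fit$W) <- rownames(V)
  colnames(fit$H) <- colnames(V)
  fit$seed <- seed
  class(fit) <- "emtsub_nmf"
  fit
}

connectivity_from_H <- function(H) {
  cl <- apply(H, 2, which.max)
  outer(cl, cl, "==") * 1
}

#' Consensus clustering over NMF restarts
#'
#' Runs `n_runs` seeded NMF restarts at rank `k`; the consensus matrix is the
#' mean over runs of the binary sample connectivity (1 iff two samples share
#' the argmax factor). Labels come from average-linkage hierarchical
#' clustering of 1 - consensus cut at k.
#'
#' @param V nonnegative matrix (genes x samples).
#' @param k rank / number of subtypes.
#' @param n_runs number of restarts (default 100).
#' @param seed master seed; restart seeds derive from it.
#' @param ... passed to [nmf_brunet()].
#' @return List of class `emtsub_subtypes`: `k`, `consensus`, `labels`,
#'   `silhouette_mean`, `restart_seeds`.
#' @export
consensus_cluster <- function(V, k, n_runs = 100L, seed = 1L, ...) {
  assert_that(n_runs >= 1, "n_runs must be >= 1")
  seeds <- vapply(seq_len(n_runs), function(r) derive_seed(seed, r * 1000L + k),
                  integer(1))
  n <- ncol(V)
  consensus <- matrix(0, n, n)
  for (s in seeds) {
    fit <- nmf_brunet(V, k, seed = s, kl_every = 0L, ...)
    consensus <- consensus + connectivity_from_H(fit$H)
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(V), colnames(V))
  hc <- hclust(as.dist(1 - consensus), method = "average")
  labels <- cutree(hc, k = k)
  if (length(unique(labels)) < k)
    stop("degenerate clustering: empty cluster at the consensus cut", call. = FALSE)
  out <- list(k = k, consensus = consensus, labels = labels,
              silhouette_mean = consensus_silhouette(consensus, labels),
              restart_seeds = seeds)
  class(out) <- "emtsub_subtypes"
  out
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Pearson correlation between the off-diagonal entries of 1 - consensus and
#' the cophenetic distances of its average-linkage dendrogram. Values near 1
#' indicate reproducible clustering.
#'
#' @param consensus symmetric consensus matrix in [0,1] with unit diagonal.
#' @return A single correlation value.
#' @export
cophenetic_coefficient <- function(consensus) {
  check_consensus(consensus)
  d <- as.dist(1 - consensus)
  if (var(as.vector(d)) == 0)
    stop("cophenetic coefficient undefined: zero-variance consensus", call. = FALSE)
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (var(as.vector(cd)) == 0) {
    # ultrametric collapse (e.g. perfect binary blocks): agreement is exact
    # when the two distance vectors coincide
    if (max(abs(as.vector(cd) - as.vector(d))) < 1e-12) return(1)
    stop("cophenetic coefficient undefined: constant dendrogram distances", call. = FALSE)
  }
  cor(as.vector(d), as.vector(cd))
}

check_consensus <- function(consensus) {
  assert_that(is.matrix(consensus) && nrow(consensus) == ncol(consensus),
              "consensus must be square")
  assert_that(max(abs(consensus - t(consensus))) < 1e-8, "consensus must be symmetric")
  assert_that(all(consensus >= -1e-12 & consensus <= 1 + 1e-12),
              "consensus entries must lie in [0,1]")
  assert_that(max(abs(diag(consensus) - 1)) < 1e-8, "consensus diagonal must be 1")
  invisible(consensus)
}

#' Dispersion of a consensus matrix
#'
#' eta = mean of 4*(c_ij - 1/2)^2 over all entries: 1 for a perfectly binary
#' consensus, 0 when every entry is 0.5.
#'
#' @param consensus matrix with entries in [0,1].
#' @return Value in [0,1].
#' @export
dispersion <- function(consensus) {
  assert_that(all(consensus >= 0 & consensus <= 1), "entries must lie in [0,1]")
  mean(4 * (consensus - 0.5)^2)
}

#' Mean silhouette width on consensus dissimilarity
#'
#' Silhouette of the labeling under distance 1 - consensus: per sample
#' (b - a)/max(a, b) with a = mean within-cluster distance, b = smallest mean
#' distance to another cluster; singleton clusters contribute width 0.
#'
#' @param consensus consensus matrix.
#' @param labels cluster assignment per sample.
#' @return Mean silhouette width.
#' @export
consensus_silhouette <- function(consensus, labels) {
  check_consensus(consensus)
  labels <- as.integer(as.factor(labels))
  assert_that(length(labels) == ncol(consensus), "one label per sample required")
  if (length(unique(labels)) < 2)
    stop("silhouette undefined for a single cluster", call. = FALSE)
  D <- 1 - consensus
  widths <- vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}

#' Consensus-NMF rank selection by cophenetic x dispersion score
#'
#' For each candidate rank, runs [consensus_cluster()] and records the
#' cophenetic correlation rho_k, the dispersion eta_k, and their product
#' (the combined score). The chosen rank is the one with the largest forward
#' drop combined_k - combined_{k+1} among ranks whose combined score exceeds
#' the grid median - i.e. the last rank before the steepest decline of the
#' combined curve. A `low_confidence` flag is raised when the chosen rank's
#' combined score falls below 0.8 (typical of unstructured data).
#'
#' @param V nonnegative matrix.
#' @param ranks candidate ranks (default 2:10).
#' @param n_runs restarts per rank (default 30).
#' @param seed master seed.
#' @param ... passed to [consensus_cluster()].
#' @return List of class `emtsub_rank_report`: `table` (rank, cophenetic,
#'   dispersion, combined), `chosen_rank`, `low_confidence`, `models`.
#' @export
select_rank <- function(V, ranks = 2:10, n_runs = 30L, seed = 1L, ...) {
  assert_that(length(ranks) >= 2, "need at least two candidate ranks")
  if (any(ranks < 2) || any(ranks >= min(dim(V))))
    stop("rank error: ranks must lie in [2, min(dim(V)) - 1]", call. = FALSE)
  ranks <- sort(ranks)
  models <- lapply(ranks, function(k) consensus_cluster(V, k, n_runs = n_runs,
                                                        seed = seed, ...))
  rho <- vapply(models, function(m) cophenetic_coefficient(m$consensus), numeric(1))
  eta <- vapply(models, function(m) dispersion(m$consensus), numeric(1))
  combined <- rho * eta
  drop_fwd <- c(combined[-length(combined)] - combined[-1], NA_real_)
  eligible <- combined > median(combined)
  eligible[length(eligible)] <- FALSE  # last rank has no forward difference
  if (!any(eligible)) eligible <- !is.na(drop_fwd)
  chosen <- ranks[eligible][which.max(drop_fwd[eligible])]
  tab <- data.frame(rank = ranks, cophenetic = rho, dispersion = eta,
                    combined = combined, forward_drop = drop_fwd)
  out <- list(table = tab, chosen_rank = chosen,
              low_confidence = combined[ranks == chosen] < 0.8,
              models = setNames(models, paste0("k", ranks)))
  class(out) <- "emtsub_rank_report"
  out
}

#' Order subtype labels along the EMT axis
#'
#' Renames clusters C1..Ck by ascending mean mesenchymal score, so C1 is the
#' most epithelial and Ck the most mesenchymal cluster. Ties in means are
#' broken by cluster size (larger first), then by lexical original id.
#'
#' @param labels cluster assignment per sample.
#' @param emt_scores one mesenchymal score per sample (same order).
#' @return List: `labels` (factor C1..Ck) and `mapping` (data.frame of
#'   original id, new name, mean score, size).
#' @export
relabel_by_emt <- function(labels, emt_scores) {
  assert_that(length(labels) == length(emt_scores), "one EMT score per sample required")
  ids <- sort(unique(as.character(labels)))
  means <- vapply(ids, function(cl) mean(emt_scores[labels == cl]), numeric(1))
  sizes <- vapply(ids, function(cl) sum(labels == cl), numeric(1))
  ord <- order(means, -sizes, ids)
  mapping <- data.frame(original = ids[ord], new = paste0("C", seq_along(ids)),
                        mean_score = means[ord], size = sizes[ord],
                        stringsAsFactors = FALSE, row.names = NULL)
  new_labels <- factor(mapping$new[match(as.character(labels), mapping$original)],
                       levels = mapping$new)
  names(new_labels) <- names(labels)
  list(labels = new_labels, mapping = mapping)
}
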