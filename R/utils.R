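#' Derive a child seed from a master seed
#'
#' Every randomized stage draws its seed from the run's master seed through a
#' splitmix-style integer hash, so adding or reordering stages never perturbs
#' the streams of the others. Results stay within the 32-bit signed range
#' accepted by [set.seed()].
#'
#' @param master integer master seed.
#' @param stream stream index (integer) or a short character tag.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stream) {
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  z <- (as.double(master) * 2654435769 + as.double(stream) * 40503 + 12345) %% 2147483647
  z <- (z * 48271) %% 2147483647
  as.integer(z)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Clip beta values away from 0 and 1 and map to M-values
#'
#' @param beta numeric vector/matrix of methylation beta values.
#' @param eps clipping bound (default 1e-6).
#' @return logit-transformed values (M-values).
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  logit(pmin(pmax(beta, eps), 1 - eps))
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

check_matrix <- function(x, name = "matrix") {
  assert_that(is.matrix(x) && is.numeric(x), paste0(name, " must be a numeric matrix"))
  assert_that(!is.null(rownames(x)) && !anyDuplicated(rownames(x)),
              paste0(name, " needs unique rownames (gene ids)"))
  assert_that(!is.null(colnames(x)) && !anyDuplicated(colnames(x)),
              paste0(name, " needs unique colnames (sample ids)"))
  assert_that(!anyNA(x), paste0(name, " contains missing values"))
  invisible(x)
}

check_beta_matrix <- function(x) {
  check_matrix(x, "beta matrix")
  assert_that(all(x >= 0 & x <= 1), "beta values must lie in [0,1]")
  invisible(x)
}

# stratified fold assignment: returns integer fold id per sample
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# stratified subsample of given fraction, returns index vector
stratified_subsample <- function(y, frac) {
  y <- as.factor(y)
  unlist(lapply(levels(y), function(lev) {
    idx <- which(y == lev)
    sample(idx, max(2L, round(frac * length(idx))))
  }), use.names = FALSE)
}

# one-vs-rest macro AUROC from posterior matrix (samples x classes)
macro_auroc <- function(post, y) {
  y <- as.factor(y)
  mean(vapply(levels(y), function(lev) {
    s <- post[, lev]
    pos <- y == lev
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- rank(s, ties.method = "average")
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }, numeric(1)), na.rm = TRUE)
}

# one-vs-rest macro area under the precision-recall curve (step integration)
macro_auprc <- function(post, y) {
  y <- as.factor(y)
  mean(vapply(levels(y), function(lev) {
    s <- post[, lev]
    pos <- y == lev
    if (!any(pos)) return(NA_real_)
    o <- order(s, decreasing = TRUE)
    tp <- cumsum(pos[o])
    prec <- tp / seq_along(tp)
    rec <- tp / sum(pos)
    sum(prec * diff(c(0, rec)))
  }, numeric(1)), na.rm = TRUE)
}

balanced_accuracy <- function(pred, y) {
  y <- as.factor(y)
  pred <- factor(pred, levels = levels(y))
  mean(vapply(levels(y), function(lev) {
    idx <- y == lev
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == lev)
  }, numeric(1)), na.rm = TRUE)
}
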