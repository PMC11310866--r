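# Empirical-Bayes moderated two-group testing for methylation matrices.
# The prior (d0, s0^2) is fitted by the method of moments on log sample
# variances (digamma/trigamma matching), the classic scaled-F hierarchy.

trigamma_inverse <- function(x) {
  # Newton iteration for y with trigamma(y) = x
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Fit the scaled inverse-chi-square prior to per-gene variances s2 with d
# residual df each. Returns d0 (possibly Inf) and s02.
fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  ev <- sum((e - ebar)^2) / (length(e) - 1) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0) {
    # log-variance spread no wider than sampling noise: full shrinkage to the
    # mean variance
    d0 <- Inf
    s02 <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    if (!is.finite(d0) || d0 <= 0) {
      warning("variance-prior moment fit non-finite; falling back to full shrinkage")
      d0 <- Inf
      s02 <- mean(s2)
    } else {
      s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t-test for two-group differential methylation
#'
#' Per-gene two-group comparison with empirical-Bayes variance shrinkage: the
#' posterior variance is s2_tilde = (d0*s02 + d*s2) / (d0 + d) with the prior
#' (d0, s02) fitted by the method of moments on log sample variances; the
#' statistic is t = delta / (s_tilde * sqrt(1/n1 + 1/n2)) on d + d0 degrees of
#' freedom. By default the test runs on M-values (logit-transformed beta,
#' clipped at 1e-6) for variance stabilization, while `delta_beta` is always
#' reported on the beta scale.
#'
#' @param beta gene-by-sample matrix (beta values in [0,1] when
#'   `use_m_values = TRUE`; any finite values otherwise).
#' @param group_labels two-level factor (or coercible) over the samples.
#' @param use_m_values test on logit-transformed values (default TRUE).
#' @return data.frame (`gene`, `delta_beta`, `t_mod`, `df_total`, `p`, `q`,
#'   `flag_zero_var`), with BH-adjusted q-values; attributes `d0` and `s02`.
#' @export
moderated_t <- function(beta, group_labels, use_m_values = TRUE) {
  check_matrix(beta, "input matrix")
  g <- as.factor(group_labels)
  assert_that(nlevels(g) == 2, "group_labels must have exactly two levels")
  assert_that(length(g) == ncol(beta), "group labels must cover all samples")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (min(n1, n2) < 2) stop("insufficient replication: need >= 2 samples per group", call. = FALSE)
  if (use_m_values) check_beta_matrix(beta)

  x <- if (use_m_values) beta_to_m(beta) else beta
  i1 <- g == levels(g)[1]; i2 <- !i1
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1, var)
  v2 <- apply(x[, i2, drop = FALSE], 1, var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  prior <- fit_variance_prior(s2, d)
  s2_tilde <- if (is.infinite(prior$d0)) rep(prior$s02, length(s2)) else
    (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
  df_total <- d + prior$d0
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  delta <- m2 - m1
  tmod <- delta / se
  p <- 2 * pt(-abs(tmod), df = df_total)
  flag <- s2 <= 0 & (is.infinite(prior$d0) == FALSE & prior$d0 == 0)
  # degenerate: zero pooled variance with no shrinkage available
  zero_var <- s2 <= 0
  if (prior$d0 == 0 || (any(zero_var) && !is.finite(prior$s02))) {
    p[zero_var] <- 1
    tmod[zero_var] <- 0
  }
  db <- rowMeans(beta[, i2, drop = FALSE]) - rowMeans(beta[, i1, drop = FALSE])
  out <- data.frame(gene = rownames(beta), delta_beta = db, t_mod = tmod,
                    df_total = df_total, p = p, q = bh_adjust(p),
                    flag_zero_var = zero_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1,
#' reported in the original gene order (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in [0,1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && all(p >= 0 & p <= 1), "p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Candidate-gene selection gate
#'
#' Retains genes with |delta_beta| strictly greater than `dbeta_min`, adjusted
#' q strictly below `q_max`, AND membership in the annotation list (the
#' EMT-associated-gene intersection), in the input gene order.
#'
#' @param dm a [moderated_t()] result table.
#' @param annotation_list character vector of eligible gene ids.
#' @param dbeta_min minimum absolute beta difference (default 0.1).
#' @param q_max maximum adjusted p (default 0.001).
#' @return Character vector of retained genes.
#' @export
select_candidates <- function(dm, annotation_list, dbeta_min = 0.1, q_max = 0.001) {
  assert_that(dbeta_min >= 0 && dbeta_min <= 1, "dbeta_min outside [0,1]")
  assert_that(q_max > 0 && q_max <= 1, "q_max outside (0,1]")
  if (length(annotation_list) == 0) {
    warning("empty annotation list: no candidates can be selected")
    return(character(0))
  }
  keep <- abs(dm$delta_beta) > dbeta_min & dm$q < q_max & dm$gene %in% annotation_list
  dm$gene[keep]
}
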