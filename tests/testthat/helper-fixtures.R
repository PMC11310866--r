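# Shared fixtures and independent brute-force oracles used across the suite.
# Everything is generated in code at test time; nothing is read from disk.

# one default-condition cohort reused by several files
default_cohort <- simulate_cohort(simulation_config(seed = 101L))

# brute-force BH step-up: q_(i) = min_{j>=i} p_(j)*m/j, original order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force cophenetic correlation: build the average-linkage dendrogram by
# explicit agglomeration and read merge heights as cophenetic distances
oracle_cophenetic <- function(consensus) {
  D <- 1 - consensus
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(NA_real_, n, n)
  active <- rep(TRUE, length(clusters))
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (a in idx) for (b in idx) if (a < b) {
      d_ab <- mean(D[clusters[[a]], clusters[[b]]])
      if (d_ab < best_d) { best_d <- d_ab; best <- c(a, b) }
    }
    for (i in clusters[[best[1]]]) for (j in clusters[[best[2]]]) {
      coph[i, j] <- coph[j, i] <- best_d
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best[2]] <- FALSE
  }
  lower <- lower.tri(D)
  cor(D[lower], coph[lower])
}

# hand silhouette on a distance matrix
oracle_silhouette <- function(D, labels) {
  mean(vapply(seq_along(labels), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

# hand-tabulated K-group log-rank chi-square (observed vs expected over the
# pooled risk set at each distinct event time)
oracle_logrank <- function(time, event, group) {
  g <- as.factor(group)
  K <- nlevels(g)
  times <- sort(unique(time[event == 1]))
  O <- E <- setNames(numeric(K), levels(g))
  V <- matrix(0, K, K)
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    for (k in levels(g)) {
      n_kt <- sum(at_risk & g == k)
      O[k] <- O[k] + sum(event == 1 & time == t & g == k)
      E[k] <- E[k] + d_t * n_kt / n_t
    }
    if (n_t > 1) {
      for (k1 in seq_len(K)) for (k2 in seq_len(K)) {
        n1 <- sum(at_risk & g == levels(g)[k1])
        n2 <- sum(at_risk & g == levels(g)[k2])
        V[k1, k2] <- V[k1, k2] +
          d_t * (n_t - d_t) / (n_t - 1) *
          (ifelse(k1 == k2, n1 / n_t, 0) - n1 * n2 / n_t^2)
      }
    }
  }
  u <- (O - E)[-1]
  chisq <- as.numeric(t(u) %*% solve(V[-1, -1]) %*% u)
  list(chisq = chisq, p = pchisq(chisq, K - 1, lower.tail = FALSE))
}

# two-sided two-sample pooled-variance t per row
oracle_pooled_t <- function(X, i1, i2) {
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(X[, i1, drop = FALSE]); m2 <- rowMeans(X[, i2, drop = FALSE])
  v1 <- apply(X[, i1, drop = FALSE], 1, var)
  v2 <- apply(X[, i2, drop = FALSE], 1, var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  (m2 - m1) / sp
}

# small labeled block-structured nonnegative matrix for clustering tests
make_blocks <- function(k = 3, per = 10, genes = 30, sep = 4, noise = 0.05,
                        seed = 1) {
  set.seed(seed)
  labels <- rep(seq_len(k), each = per)
  mu <- matrix(0.1, genes, k)
  for (c in seq_len(k)) {
    rows <- ((c - 1) * (genes %/% k) + 1):(c * (genes %/% k))
    mu[rows, c] <- 0.1 + sep * noise
  }
  V <- pmax(mu[, labels] + matrix(rnorm(genes * k * per, 0, noise), genes), 1e-4)
  dimnames(V) <- list(sprintf("g%02d", seq_len(genes)), sprintf("s%02d", seq_along(labels)))
  list(V = V, labels = labels)
}
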