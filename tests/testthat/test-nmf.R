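test_that("input domain is validated", {
  V <- matrix(runif(40), 8, 5)
  Vneg <- V; Vneg[1, 1] <- -0.1
  expect_error(nmf_brunet(Vneg, 2), "negative")
  expect_error(nmf_brunet(V, 5), "rank error")
  Vzero <- V; Vzero[, 3] <- 0
  expect_error(nmf_brunet(Vzero, 2), "all-zero")
})

test_that("KL divergence is non-increasing and exact factorizations are recovered", {
  set.seed(17)
  for (i in 1:5) {
    V <- matrix(runif(30 * 12, 0.05, 1), 30, 12)
    fit <- nmf_brunet(V, 3, seed = i)
    expect_true(all(diff(fit$kl_trace) <= 1e-9))
  }
  # exact rank-2 product: residual KL tiny relative to mass
  set.seed(18)
  W0 <- matrix(runif(40 * 2, 0.1, 1), 40, 2)
  H0 <- matrix(runif(2 * 15, 0.1, 1), 2, 15)
  V <- W0 %*% H0
  kls <- vapply(1:5, function(s) {
    tail(nmf_brunet(V, 2, seed = s, max_iter = 5000, conn_stop = 1e6)$kl_trace, 1)
  }, numeric(1))
  expect_lt(min(kls), 1e-6 * sum(V))
})

test_that("connectivity is equivariant to rescaling of V", {
  set.seed(19)
  V <- matrix(runif(30 * 12, 0.05, 1), 30, 12)
  f1 <- nmf_brunet(V, 3, seed = 4)
  f2 <- nmf_brunet(10 * V, 3, seed = 4)
  expect_identical(apply(f1$H, 2, which.max), apply(f2$H, 2, which.max))
})

test_that("consensus clustering has unit diagonal, binary single-run entries, and block structure", {
  blocks <- make_blocks(seed = 2)
  one <- consensus_cluster(blocks$V, 3, n_runs = 1, seed = 5)
  expect_true(all(one$consensus %in% c(0, 1)))
  expect_true(all(diag(one$consensus) == 1))
  cc <- consensus_cluster(blocks$V, 3, n_runs = 20, seed = 5)
  same <- outer(blocks$labels, blocks$labels, "==")
  off <- !diag(nrow(cc$consensus))
  expect_gt(mean(cc$consensus[same & off]), 0.95)
  expect_lt(mean(cc$consensus[!same]), 0.05)
  expect_gte(mclust::adjustedRandIndex(cc$labels, blocks$labels), 1)
})

test_that("dispersion matches hand-evaluated and boundary cases", {
  expect_equal(dispersion(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_equal(dispersion(matrix(0.5, 3, 3)), 0)
  expect_equal(dispersion(matrix(c(1, 0.75, 0.75, 1), 2)), 0.625)
})

test_that("cophenetic coefficient matches a brute-force dendrogram oracle", {
  C4 <- matrix(c(1, .9, .1, .1,
                 .9, 1, .1, .1,
                 .1, .1, 1, .8,
                 .1, .1, .8, 1), 4, 4)
  expect_equal(cophenetic_coefficient(C4), oracle_cophenetic(C4), tolerance = 1e-12)
  # random symmetric consensus matrices
  set.seed(23)
  for (i in 1:5) {
    n <- 6
    M <- matrix(runif(n * n), n)
    C <- (M + t(M)) / 2
    diag(C) <- 1
    expect_equal(cophenetic_coefficient(C), oracle_cophenetic(C), tolerance = 1e-10)
  }
  # perfect binary blocks are ultrametric
  Cp <- (outer(rep(1:2, each = 3), rep(1:2, each = 3), "==")) * 1
  diag(Cp) <- 1
  expect_equal(cophenetic_coefficient(Cp), 1)
  # shift invariance of the correlation
  C4b <- pmin(pmax(C4 + 0.05, 0), 1); diag(C4b) <- 1
  expect_equal(cophenetic_coefficient(C4), cophenetic_coefficient(C4b),
               tolerance = 1e-10)
  expect_error(cophenetic_coefficient(matrix(1, 3, 3)), "zero-variance")
})

test_that("consensus silhouette matches hand computation and degrades under misassignment", {
  Cp <- (outer(rep(1:2, each = 3), rep(1:2, each = 3), "==")) * 1
  diag(Cp) <- 1
  expect_equal(consensus_silhouette(Cp, rep(1:2, each = 3)), 1)
  # 3-sample toy, hand-set consensus
  C3 <- matrix(c(1, .8, .2,
                 .8, 1, .3,
                 .2, .3, 1), 3, 3)
  lab <- c(1, 1, 2)
  expect_equal(consensus_silhouette(C3, lab), oracle_silhouette(1 - C3, lab),
               tolerance = 1e-12)
  blocks <- make_blocks(seed = 3)
  cc <- consensus_cluster(blocks$V, 3, n_runs = 10, seed = 2)
  set.seed(9)
  rand_lab <- sample(blocks$labels)
  expect_lt(consensus_silhouette(cc$consensus, rand_lab), 0.1)
  expect_error(consensus_silhouette(Cp, rep(1, 6)), "single cluster")
})

test_that("rank selection recovers planted k and flags unstructured data", {
  blocks <- make_blocks(k = 2, per = 8, genes = 24, seed = 4)
  rk2 <- select_rank(blocks$V, ranks = 2:5, n_runs = 10, seed = 3)
  expect_equal(rk2$chosen_rank, 2)
  expect_false(rk2$low_confidence)
  set.seed(6)
  noise <- matrix(runif(30 * 16, 0.2, 0.8), 30, 16,
                  dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:16)))
  rkn <- select_rank(noise, ranks = 2:4, n_runs = 10, seed = 3)
  expect_true(rkn$low_confidence)
})

test_that("EMT relabeling orders clusters deterministically", {
  labels <- c(a = "x", b = "x", c = "y", d = "y", e = "y")
  scores <- c(0.5, 0.7, -0.5, -0.6, -0.4)
  rel <- relabel_by_emt(labels, scores)
  expect_identical(as.character(rel$labels), c("C2", "C2", "C1", "C1", "C1"))
  # ties: larger cluster first
  s2 <- c(1, 1, 1, 1, 1)
  rel2 <- relabel_by_emt(labels, s2)
  expect_identical(rel2$mapping$original[1], "y")
  # invariance under permuted cluster ids
  labels_p <- c(a = "q", b = "q", c = "p", d = "p", e = "p")
  rel3 <- relabel_by_emt(labels_p, scores)
  expect_identical(as.character(rel3$labels), as.character(rel$labels))
})
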