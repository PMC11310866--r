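make_labeled <- function(n_per = 20, p = 40, shift = 1.5, n_shift = 6, seed = 1,
                         classes = c("A", "B")) {
  set.seed(seed)
  n <- n_per * length(classes)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%03d", 1:p), sprintf("S%03d", 1:n)))
  y <- factor(rep(classes, each = n_per))
  if (n_shift > 0) X[1:n_shift, y == classes[2]] <- X[1:n_shift, y == classes[2]] + shift
  list(X = X, y = y, shifted = rownames(X)[seq_len(n_shift)])
}

test_that("SAM with s0 = 0 reduces to the ordinary pooled-variance t", {
  d <- make_labeled(seed = 2)
  sam <- sam_statistic(d$X, d$y, seed = 1, s0 = 0)
  tord <- oracle_pooled_t(d$X, d$y == "A", d$y == "B")
  expect_equal(sam$d, unname(tord), tolerance = 1e-12)
})

test_that("SAM is calibrated under the null and recovers planted shifts", {
  null <- make_labeled(p = 500, n_shift = 0, seed = 3, n_per = 20)
  sam0 <- sam_statistic(null$X, null$y, seed = 4)
  expect_lte(mean(sam0$q < 0.05), 0.07)
  alt <- make_labeled(p = 200, n_per = 40, shift = 2, n_shift = 20, seed = 5)
  sam1 <- sam_statistic(alt$X, alt$y, seed = 6)
  expect_gte(mean(alt$shifted %in% sam1$gene[sam1$q < 0.05]), 0.9)
})

test_that("maxT adjustment dominates raw p and matches exhaustive enumeration", {
  d <- make_labeled(p = 30, seed = 7)
  mx <- maxt_adjust(d$X, d$y, seed = 8)
  expect_true(all(mx$adj_p >= mx$raw_p - 1e-12))
  # single gene: no multiplicity
  d1 <- make_labeled(p = 1, n_shift = 0, seed = 9)
  mx1 <- maxt_adjust(d1$X, d1$y, seed = 10)
  expect_equal(mx1$adj_p, mx1$raw_p)
  # exhaustive oracle at n = 6 (two null genes, all 20 balanced relabelings)
  set.seed(11)
  X6 <- matrix(rnorm(12), 2, 6, dimnames = list(c("g1", "g2"), sprintf("S%d", 1:6)))
  y6 <- factor(rep(c("a", "b"), each = 3))
  combs <- combn(6, 3)
  perms <- t(apply(combs, 2, function(idx) c(idx, setdiff(1:6, idx))))
  mx6 <- maxt_adjust(X6, y6, perms = perms)
  # brute force: all balanced assignments
  t_all <- sapply(seq_len(nrow(perms)), function(i) {
    yy <- y6[perms[i, ]]
    abs(oracle_pooled_t(X6, yy == "a", yy == "b"))
  })
  tobs <- abs(oracle_pooled_t(X6, y6 == "a", y6 == "b"))
  maxT <- apply(t_all, 2, max)
  expected_adj <- (1 + sapply(tobs, function(t0) sum(maxT >= t0 - 1e-12))) / (1 + ncol(t_all))
  o <- order(-tobs)
  expected_adj[o] <- cummax(expected_adj[o])
  expect_equal(mx6$adj_p, unname(expected_adj))
})

test_that("consensus DA intersects the three algorithms and collapses under shuffling", {
  set.seed(12)
  n_per <- 25
  X <- matrix(rnorm(80 * 3 * n_per), 80, 3 * n_per,
              dimnames = list(sprintf("g%03d", 1:80), sprintf("S%03d", 1:(3 * n_per))))
  y <- factor(rep(c("C1", "C2", "C3"), each = n_per))
  planted <- sprintf("g%03d", 1:9)
  for (i in 1:9) {
    cl <- c("C1", "C2", "C3")[(i - 1) %% 3 + 1]
    X[planted[i], y == cl] <- X[planted[i], y == cl] + 1.5
  }
  da <- consensus_da(X, y, seed = 13)
  hit <- da$consensus_da_genes
  expect_gte(mean(planted %in% hit), 0.85)
  expect_gte(mean(hit %in% planted), 0.9)
  # shuffled labels: empty consensus in most seeds
  empties <- vapply(1:8, function(s) {
    set.seed(100 + s)
    ys <- sample(y)
    suppressWarnings(length(consensus_da(X, ys, seed = s)$consensus_da_genes) == 0)
  }, logical(1))
  expect_gte(mean(empties), 7 / 8)
})

test_that("logistic QC retains true predictors and discards noise", {
  set.seed(14)
  n <- 60
  y <- factor(rep(c("C1", "C2"), each = n / 2))
  X <- rbind(perfect = as.numeric(y == "C2") * 2 - 1 + rnorm(n, 0, 0.01),
             noise1 = rnorm(n), noise2 = rnorm(n))
  colnames(X) <- sprintf("S%03d", 1:n)
  qc <- logistic_qc(X, y, rownames(X), n_iter = 100, seed = 15)
  expect_equal(unname(qc$frequency["perfect"]), 1)
  expect_true("perfect" %in% qc$leaf_genes)
  expect_false("noise1" %in% qc$leaf_genes)
  expect_lt(qc$frequency[["noise1"]], 0.3)
  # single iteration degenerates to one significance screen
  qc1 <- logistic_qc(X, y, rownames(X), n_iter = 1, subsample = 1, seed = 16)
  expect_true("perfect" %in% qc1$leaf_genes)
})

test_that("correlation filter removes collinear duplicates deterministically", {
  set.seed(17)
  base <- rnorm(50)
  X <- rbind(a = base, b = base, c = rnorm(50), d = base * 0.97 + rnorm(50, 0, 0.07))
  colnames(X) <- sprintf("S%02d", 1:50)
  kept <- correlation_filter(X, rownames(X), r_max = 0.9)
  expect_length(setdiff(c("a", "b"), kept), 1)  # exactly one copy kept
  expect_true("c" %in% kept)
  # r_max = 1: only exact collinearity removed
  kept1 <- correlation_filter(X, rownames(X), r_max = 1)
  expect_setequal(setdiff(rownames(X), kept1), "b")
  # 3-gene case against exhaustive maximal-set search: one collinear pair plus
  # an independent gene leaves exactly two genes, matching the best subset
  X3 <- X[c("a", "d", "c"), ]
  kept3 <- correlation_filter(X3, rownames(X3), r_max = 0.9)
  r3 <- cor(t(X3))
  subsets <- list(c("a"), c("d"), c("c"), c("a", "d"), c("a", "c"),
                  c("d", "c"), c("a", "d", "c"))
  admissible <- Filter(function(s) {
    all(abs(r3[s, s][upper.tri(diag(length(s)))]) <= 0.9)
  }, subsets)
  best_size <- max(lengths(admissible))
  expect_length(kept3, best_size)
  expect_true(all(abs(r3[kept3, kept3][upper.tri(diag(length(kept3)))]) <= 0.9))
})

test_that("Boruta confirms strong signals and rejects pure noise", {
  set.seed(18)
  n <- 80
  y <- factor(rep(c("C1", "C2"), each = n / 2))
  X <- rbind(signal = as.numeric(y == "C2") + rnorm(n, 0, 0.05),
             matrix(rnorm(9 * n), 9, n,
                    dimnames = list(paste0("noise", 1:9), NULL)))
  colnames(X) <- sprintf("S%03d", 1:n)
  res <- boruta_select(X, y, max_rounds = 15, seed = 19)
  expect_true("signal" %in% res$confirmed)
  noise_only <- X[-1, , drop = FALSE]
  res0 <- suppressWarnings(boruta_select(noise_only, y, max_rounds = 15, seed = 20))
  expect_length(res0$confirmed, 0)
  # a feature never beating the max shadow cannot be confirmed
  zero_hit <- names(res0$hits)[res0$hits == 0]
  expect_true(all(zero_hit %in% res0$rejected))
})

test_that("SVM-RFE eliminates the informative gene last", {
  set.seed(21)
  n <- 60
  y <- factor(rep(c("C1", "C2"), each = n / 2))
  X <- rbind(info = as.numeric(y == "C2") * 3 + rnorm(n, 0, 0.1),
             matrix(rnorm(9 * n), 9, n, dimnames = list(paste0("n", 1:9), NULL)))
  colnames(X) <- sprintf("S%03d", 1:n)
  r <- svm_rfe(X, y, step_frac = 0.1)
  expect_equal(r$ranking[1], "info")
  # exactly 3 rounds when one gene is removed per round from 3 genes
  r3 <- svm_rfe(X[1:3, ], y, step_frac = 0.2)
  expect_length(r3$elimination_order, 3)
  # rescaling a feature does not change its rank (standardization)
  X2 <- X; X2["n3", ] <- X2["n3", ] * 100
  r2 <- svm_rfe(X2, y, step_frac = 0.1)
  expect_equal(r2$ranking[1], "info")
  expect_error(svm_rfe(X, y, target_size = 99), "size error")
})

test_that("sparse group lasso matches an unpenalized multinomial oracle at lambda = 0", {
  skip_if_not_installed("nnet")
  set.seed(22)
  n <- 60; p <- 4
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- factor(sample(c("A", "B", "C"), n, TRUE))
  f <- sgl_fit(X, y, lambda = 0, alpha = 0.95, max_iter = 200000L, tol = 1e-9)
  m <- nnet::multinom(y ~ X, trace = FALSE, maxit = 1000, reltol = 1e-14)
  Bm <- cbind(A = 0, t(coef(m))[-1, ])
  expect_lt(max(abs((f$B - rowMeans(f$B)) - (Bm - rowMeans(Bm)))), 1e-4)
  # total shrinkage at huge lambda
  f_inf <- sgl_fit(X, y, lambda = 1e6, alpha = 0.95)
  expect_true(all(abs(f_inf$B) < 1e-12))
  expect_false(any(f_inf$selected))
})

test_that("stability selection recovers a planted discriminative panel", {
  set.seed(23)
  n_per <- 50
  y <- factor(rep(c("C1", "C2", "C3"), each = n_per))
  n <- length(y)
  X <- matrix(rnorm(60 * n), 60, n,
              dimnames = list(sprintf("g%03d", 1:60), sprintf("S%03d", 1:n)))
  planted <- sprintf("g%03d", 1:6)
  for (i in 1:6) {
    cl <- levels(y)[(i - 1) %% 3 + 1]
    X[planted[i], y == cl] <- X[planted[i], y == cl] + 1.5
  }
  st <- msgl_stability(X, y, n_runs = 20, seed = 24)
  expect_true(all(planted %in% st$panel_genes))
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
  expect_true(all(st$frequency[planted] >= 0.5))
})

test_that("panel trace preserves stage monotonicity", {
  co <- simulate_cohort(simulation_config(seed = 33L,
                                          n_per_cluster = c(30L, 30L, 30L),
                                          n_genes = 120L, n_informative = 15L))
  tr <- suppressMessages(derive_panel(co$expression, paste0("C", co$true_labels),
                                      seed = 34, qc_iter = 100,
                                      stability_runs = 20))
  expect_true(all(tr$leaf_genes %in% tr$consensus_da_genes))
  expect_true(all(tr$post_correlation_genes %in% tr$leaf_genes))
  expect_true(all(tr$wrapper_genes %in% tr$post_correlation_genes))
  expect_true(all(tr$panel_genes %in% tr$wrapper_genes))
  expect_true(all(tr$selection_frequency >= 0 & tr$selection_frequency <= 1))
})
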