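make_expr <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

test_that("KS score matches brute-force ECDF distances and its bounds", {
  # one sample: E = {1,2,3}, M = {2,3,4}
  expr <- make_expr(c(1, 2, 3, 2, 3, 4), c(paste0("e", 1:3), paste0("m", 1:3)), "S1")
  got <- score_ks(expr, paste0("e", 1:3), paste0("m", 1:3))
  grid <- c(1, 2, 3, 4)
  Fe <- sapply(grid, function(t) mean(c(1, 2, 3) <= t))
  Fm <- sapply(grid, function(t) mean(c(2, 3, 4) <= t))
  expect_equal(unname(got), max(Fe - Fm) - max(Fm - Fe))
  # complete separation: every M value above every E value
  expr2 <- make_expr(c(1, 2, 3, 5, 6, 7), rownames(expr), "S1")
  expect_equal(unname(score_ks(expr2, paste0("e", 1:3), paste0("m", 1:3))), 1)
  # null: same distribution -> mean near 0 over seeds
  set.seed(3)
  sc <- replicate(50, {
    e3 <- make_expr(rnorm(10), c(paste0("e", 1:5), paste0("m", 1:5)), "S1")
    score_ks(e3, paste0("e", 1:5), paste0("m", 1:5))
  })
  expect_lt(abs(mean(sc)), 0.1)
  expect_true(all(abs(sc) <= 1))
  expect_error(score_ks(expr, c("e1", "e2"), paste0("m", 1:3)), "insufficient signature")
})

test_that("KS and ssGSEA are invariant to per-sample monotone transforms", {
  set.seed(5)
  expr <- make_expr(rnorm(200), sprintf("g%03d", 1:20), sprintf("S%02d", 1:10))
  es <- sprintf("g%03d", 1:5); ms <- sprintf("g%03d", 6:10)
  sets <- list(A = es, B = ms)
  transformed <- exp(expr / 2) + 1
  expect_equal(score_ks(expr, es, ms), score_ks(transformed, es, ms))
  expect_equal(ssgsea(expr, sets), ssgsea(transformed, sets))
  # rank replacement leaves ssGSEA unchanged
  ranked <- apply(expr, 2, rank)
  dimnames(ranked) <- dimnames(expr)
  expect_equal(ssgsea(expr, sets), ssgsea(ranked, sets))
})

test_that("76-gene score weights genes by correlation with the anchor", {
  set.seed(7)
  ref <- rnorm(30)
  expr <- rbind(ref = ref, g1 = ref * 2 + 1, g2 = -ref + rnorm(30, 0, 1e-6))
  colnames(expr) <- sprintf("S%02d", 1:30)
  sig <- c("ref", "g1", "g2", paste0("x", 1:10))
  expr <- rbind(expr, matrix(rep(ref, 10), 10, 30, byrow = TRUE,
                             dimnames = list(paste0("x", 1:10), colnames(expr))))
  sc <- score_76gs(expr, sig, "ref")
  w <- attr(sc, "weights")
  expect_lt(w[["g2"]], 0)
  expect_gt(w[["g1"]], 0.99)
  # perfectly correlated signature: score proportional to unweighted sum
  expr_pc <- expr[c("ref", "g1", paste0("x", 1:10)), ]
  sc_pc <- score_76gs(expr_pc, rownames(expr_pc), "ref")
  unweighted <- colSums(expr_pc)
  expect_gt(cor(as.vector(sc_pc), unweighted), 0.999)
  # sample permutation permutes scores identically
  perm <- c(5:30, 1:4)
  sc_perm <- score_76gs(expr[, perm], sig, "ref")
  expect_equal(as.vector(sc_perm), as.vector(sc)[perm])
  expect_error(score_76gs(expr, sig, "absent_gene"), "absent")
})

test_that("mean-difference score is exact and shift-invariant", {
  expr <- make_expr(c(2, 2, 5, 5), c("e1", "e2", "m1", "m2"), "S1")
  expect_equal(unname(score_mlr(expr, c("e1", "e2"), c("m1", "m2"))), 3)
  expect_equal(score_mlr(expr, c("e1", "m1"), c("e1", "m1")),
               c(S1 = 0))
  expect_equal(score_mlr(expr + 7, c("e1", "e2"), c("m1", "m2")),
               score_mlr(expr, c("e1", "e2"), c("m1", "m2")))
})

test_that("ssGSEA equals the hand-walked running sum on a 5-gene toy", {
  # expression ranks genes g1 > g2 > g3 > g4 > g5; set = {g1, g2, g5}
  expr <- make_expr(c(5, 4, 3, 2, 1), paste0("g", 1:5), "S1")
  alpha <- 0.25
  rank_val <- (5:1)^alpha
  inset <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  p_in <- cumsum(rank_val * inset) / sum(rank_val * inset)
  p_out <- cumsum(!inset) / sum(!inset)
  expected <- sum(p_in - p_out)
  got <- ssgsea(expr, list(s = c("g1", "g2", "g5")), alpha = alpha)
  expect_equal(unname(got["s", "S1"]), expected)
  # the top-ranked singleton set dominates all other singletons
  singles <- ssgsea(expr, setNames(lapply(paste0("g", 1:5), identity),
                                   paste0("set", 1:5)))
  expect_equal(which.max(singles[, "S1"]), c(set1 = 1))
  expect_error(ssgsea(expr, list(s = paste0("g", 1:5))), "degenerate")
  expect_error(ssgsea(expr, list(s = "unknown")), "empty set")
})

test_that("the planted mesenchymal subtype ranks highest on KS/MLR and lowest on 76GS", {
  co <- default_cohort
  es <- co$gene_sets$epithelial; ms <- co$gene_sets$mesenchymal
  ks <- score_ks(co$expression, es, ms)
  mlr <- score_mlr(co$expression, es, ms)
  gs <- score_76gs(co$expression, c(es, ms), es[1])
  mes <- co$true_labels == co$mesenchymal_cluster
  for (other in setdiff(unique(co$true_labels), co$mesenchymal_cluster)) {
    idx <- co$true_labels == other
    expect_lt(wilcox.test(ks[mes], ks[idx], alternative = "greater", exact = FALSE)$p.value, 0.01)
    expect_lt(wilcox.test(mlr[mes], mlr[idx], alternative = "greater", exact = FALSE)$p.value, 0.01)
    expect_lt(wilcox.test(as.vector(gs)[mes], as.vector(gs)[idx],
                          alternative = "less")$p.value, 0.01)
  }
})
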