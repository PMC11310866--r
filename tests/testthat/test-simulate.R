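test_that("same seed and config reproduce the cohort bit-identically", {
  a <- simulate_cohort(simulation_config(seed = 7L))
  b <- simulate_cohort(simulation_config(seed = 7L))
  expect_identical(a$beta, b$beta)
  expect_identical(a$expression, b$expression)
  expect_identical(a$survival, b$survival)
  expect_identical(a$drug_response, b$drug_response)
  d <- simulate_cohort(simulation_config(seed = 8L))
  expect_false(identical(a$beta, d$beta))
})

test_that("beta values stay strictly inside (0,1) and planted shifts are recoverable", {
  co <- default_cohort
  expect_true(min(co$beta) > 0 && max(co$beta) < 1)
  expect_true(min(co$beta_normal) > 0 && max(co$beta_normal) < 1)
  # per informative gene: target-cluster mean minus other-cluster mean
  info <- co$gene_info[co$gene_info$informative, ]
  diffs <- vapply(seq_len(nrow(info)), function(i) {
    tgt <- co$true_labels == info$cluster[i]
    abs(mean(co$beta[info$gene[i], tgt]) - mean(co$beta[info$gene[i], !tgt]))
  }, numeric(1))
  expect_gte(mean(diffs), 0.2)
})

test_that("delta_beta = 0 leaves informative genes indistinguishable from noise", {
  cfg <- simulation_config(seed = 5L, n_per_cluster = c(60L, 60L),
                           delta_beta = 0, hazard_ratios = c(1, 1))
  meth <- simulate_methylation(cfg)
  g1 <- meth$true_labels == 1
  pvals <- apply(meth$beta, 1, function(x) t.test(x[g1], x[!g1])$p.value)
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_per_cluster = c(40, 0)), "non-positive")
  expect_error(simulation_config(delta_beta = 0.7), "delta_beta")
  expect_error(simulation_config(censor_rate = 1), "censor_rate")
  expect_error(simulation_config(hazard_ratios = c(1, -1, 1)), "hazard")
  expect_error(simulation_config(n_informative = 500, n_genes = 100), "n_informative")
})

test_that("expression couples inversely to driver methylation", {
  cfg <- simulation_config(seed = 11L, expr_coupling = 2, expr_noise_sd = 0.1)
  meth <- simulate_methylation(cfg)
  ex <- simulate_expression(meth$beta, meth$true_labels, cfg, meth$gene_info)
  rs <- vapply(meth$informative_genes, function(g) {
    cor(meth$beta[g, ], ex$expression[g, ])
  }, numeric(1))
  expect_true(all(rs < -0.8))
  # zero coupling: no association
  cfg0 <- simulation_config(seed = 11L, expr_coupling = 0)
  ex0 <- simulate_expression(meth$beta, meth$true_labels, cfg0, meth$gene_info)
  rs0 <- vapply(meth$informative_genes, function(g) {
    cor(meth$beta[g, ], ex0$expression[g, ])
  }, numeric(1))
  expect_lt(mean(abs(rs0)), 0.15)
})

test_that("constant methylation yields pure-noise expression at the configured scale", {
  cfg <- simulation_config(seed = 3L, expr_noise_sd = 0.3)
  n <- sum(cfg$n_per_cluster)
  beta <- matrix(0.4, 50, n, dimnames = list(sprintf("g%04d", 1:50),
                                             sprintf("S%03d", 1:n)))
  labels <- setNames(rep(1L, n), colnames(beta))
  ex <- simulate_expression(beta, labels, cfg)
  vars <- apply(ex$expression, 1, var)
  expect_lt(abs(mean(vars) - cfg$expr_noise_sd^2), 0.02)
})

test_that("expression simulation rejects misaligned ids", {
  co <- default_cohort
  bad <- co$true_labels
  names(bad) <- rev(names(bad))
  expect_error(simulate_expression(co$beta, bad, co$config), "alignment")
})

test_that("survival respects censoring rate and planted hazards", {
  cfg0 <- simulation_config(seed = 2L, censor_rate = 0)
  labels <- setNames(rep(1:3, each = 40), sprintf("S%03d", 1:120))
  s0 <- simulate_survival(labels, cfg0)
  expect_true(all(s0$event == 1))
  expect_true(all(s0$time > 0))
  # achieved censoring close to target on a larger draw
  cfg <- simulation_config(seed = 2L, n_per_cluster = c(200L, 200L, 200L),
                           censor_rate = 0.3)
  big_labels <- setNames(rep(1:3, each = 200), sprintf("S%03d", 1:600))
  s1 <- simulate_survival(big_labels, cfg)
  expect_lt(abs(mean(1 - s1$event) - 0.3), 0.06)
})

test_that("log-rank is non-significant under equal hazards and powered under HR 3", {
  null_p <- vapply(1:40, function(s) {
    cfg <- simulation_config(seed = 1000L + s, n_per_cluster = c(60L, 60L),
                             hazard_ratios = c(1, 1))
    labels <- setNames(rep(1:2, each = 60), sprintf("S%03d", 1:120))
    sv <- simulate_survival(labels, cfg)
    logrank_test(sv, labels)$p
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.9)
  alt_p <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = 2000L + s, n_per_cluster = c(200L, 200L),
                             hazard_ratios = c(1, 3))
    labels <- setNames(rep(1:2, each = 200), sprintf("S%03d", 1:400))
    sv <- simulate_survival(labels, cfg)
    logrank_test(sv, labels)$p
  }, numeric(1))
  expect_gte(mean(alt_p < 0.01), 0.9)
})

test_that("drug responses are linear in their signatures and recoverable", {
  cfg <- simulation_config(seed = 4L, drug_noise_sd = 0)
  ph <- simulate_pharmacogenomics(cfg)
  # noiseless: ordinary least squares on the signature recovers unit weights
  d1 <- ph$response[ph$response$drug == "drug01", ]
  Xs <- t(ph$expression[ph$signatures$drug01, d1$line])
  fit <- lm(d1$response ~ Xs)
  expect_lt(max(abs(coef(fit)[-1] - 1)), 1e-8)
  # over-budget disjoint signatures rejected
  expect_error(simulate_pharmacogenomics(
    simulation_config(n_drugs = 40L, drug_signature_size = 10L, n_genes = 300L)),
    "gene budget")
})

test_that("held-out drug prediction works at noise = half signal, dies under permutation", {
  # signal sd for 10 unit-weight genes of unit sd is ~sqrt(10); noise ~ half of
  # it; 100 training lines over a 100-gene space
  cfg <- simulation_config(seed = 101L, n_cell_lines = 160L, n_genes = 100L,
                           drug_noise_sd = 1.58)
  ph <- simulate_pharmacogenomics(cfg)
  d1 <- ph$response[ph$response$drug == "drug01", ]
  tr_lines <- d1$line[1:100]; te_lines <- d1$line[101:160]
  tr <- ridge_transfer(ph$expression[, tr_lines], d1[d1$line %in% tr_lines, ],
                       ph$expression[, te_lines], seed = 1)
  r <- cor(tr$predictions["drug01", ], d1$response[match(te_lines, d1$line)])
  expect_gt(r, 0.6)
  # permuting responses destroys predictability
  set.seed(1)
  d1p <- d1[d1$line %in% tr_lines, ]
  d1p$response <- sample(d1p$response)
  trp <- ridge_transfer(ph$expression[, tr_lines], d1p,
                        ph$expression[, te_lines], seed = 1)
  rp <- cor(trp$predictions["drug01", ], d1$response[match(te_lines, d1$line)])
  expect_lt(abs(rp), 0.35)
})

test_that("cohort files round-trip through the plain-text writers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(simulation_config(seed = 9L, n_per_cluster = c(10L, 10L, 10L),
                                          n_genes = 60L, n_informative = 18L,
                                          n_normal = 10L, n_cell_lines = 30L))
  suppressMessages(paths <- write_cohort(co, dir))
  expect_equal(read_matrix_tsv(paths["beta"]), co$beta)
  expect_equal(read_matrix_tsv(paths["expression"]), co$expression)
  sets <- read_gmt(paths["gene_sets"])
  expect_identical(sets[["mesenchymal"]], co$gene_sets$mesenchymal)
  clin <- read_clinical_tsv(paths["clinical"])
  expect_equal(clin$time, co$survival$time)
})
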