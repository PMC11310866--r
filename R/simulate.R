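#' Simulation configuration for synthetic methylation cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults define the study conditions used throughout the package's tests
#' and analysis scripts: three balanced subtypes of 40 samples, 300 genes of
#' which 60 carry a planted promoter-methylation shift of 0.25 on the beta
#' scale, inverse methylation-expression coupling for driver genes,
#' subtype-dependent exponential survival with ~30% uniform censoring, and a
#' small cell-line pharmacogenomic panel whose drug responses are linear in
#' disjoint 10-gene expression signatures.
#'
#' @param seed master seed; all stage seeds derive from it via [derive_seed()].
#' @param n_per_cluster integer vector of per-subtype sample counts.
#' @param n_genes total number of genes.
#' @param n_informative number of genes with a planted subtype shift.
#' @param delta_beta planted effect size on the beta scale, in [0, 0.5].
#' @param beta_noise_sd Gaussian noise sd on the logit (M-value) scale.
#' @param expr_coupling slope linking driver-gene methylation to expression
#'   (expression = intercept - expr_coupling * beta + noise).
#' @param expr_noise_sd Gaussian noise sd of log-expression.
#' @param censor_rate target fraction of censored samples, in [0, 1).
#' @param hazard_ratios per-subtype hazard multipliers (positive).
#' @param baseline_hazard exponential baseline hazard (events per time unit).
#' @param n_cell_lines number of cell lines in the pharmacogenomic panel.
#' @param n_drugs number of drugs.
#' @param drug_signature_size genes per drug signature (disjoint across drugs).
#' @param drug_noise_sd Gaussian noise sd of drug response.
#' @param purity_effect sd of per-gene purity-confounding slopes injected into
#'   tumor expression (0 disables the confounder).
#' @param n_normal number of adjacent-normal samples for the
#'   tumor-vs-normal differential filter (see
#'   [simulate_normal_methylation()] for the planted offset).
#' @return A validated list of class `emtsub_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_per_cluster = c(40L, 40L, 40L),
                              n_genes = 300L,
                              n_informative = 60L,
                              delta_beta = 0.25,
                              beta_noise_sd = 0.5,
                              expr_coupling = 2,
                              expr_noise_sd = 0.3,
                              censor_rate = 0.3,
                              hazard_ratios = c(1, 1.5, 2.5),
                              baseline_hazard = 0.08,
                              n_cell_lines = 100L,
                              n_drugs = 5L,
                              drug_signature_size = 10L,
                              drug_noise_sd = 1,
                              purity_effect = 0.5,
                              n_normal = 40L) {
  cfg <- list(seed = as.integer(seed), n_per_cluster = as.integer(n_per_cluster),
              n_genes = as.integer(n_genes), n_informative = as.integer(n_informative),
              delta_beta = delta_beta, beta_noise_sd = beta_noise_sd,
              expr_coupling = expr_coupling, expr_noise_sd = expr_noise_sd,
              censor_rate = censor_rate, hazard_ratios = hazard_ratios,
              baseline_hazard = baseline_hazard, n_cell_lines = as.integer(n_cell_lines),
              n_drugs = as.integer(n_drugs),
              drug_signature_size = as.integer(drug_signature_size),
              drug_noise_sd = drug_noise_sd, purity_effect = purity_effect,
              n_normal = as.integer(n_normal))
  if (any(cfg$n_per_cluster <= 0)) stop("invalid config: non-positive cluster size", call. = FALSE)
  assert_that(cfg$n_genes > 0 && cfg$n_informative >= 0, "invalid config: counts must be positive")
  assert_that(cfg$n_informative <= cfg$n_genes, "invalid config: n_informative > n_genes")
  assert_that(cfg$delta_beta >= 0 && cfg$delta_beta <= 0.5, "invalid config: delta_beta outside [0, 0.5]")
  assert_that(cfg$beta_noise_sd > 0, "invalid config: beta_noise_sd must be positive")
  assert_that(cfg$censor_rate >= 0 && cfg$censor_rate < 1, "invalid config: censor_rate outside [0,1)")
  assert_that(all(cfg$hazard_ratios > 0), "invalid config: hazard ratios must be positive")
  assert_that(length(cfg$hazard_ratios) == length(cfg$n_per_cluster),
              "invalid config: one hazard ratio per subtype required")
  assert_that(cfg$n_cell_lines > 0 && cfg$n_drugs > 0 && cfg$drug_signature_size > 0,
              "invalid config: counts must be positive")
  assert_that(cfg$drug_noise_sd >= 0, "invalid config: drug_noise_sd must be non-negative")
  class(cfg) <- "emtsub_config"
  cfg
}

gene_ids_for <- function(n) sprintf("g%04d", seq_len(n))
sample_ids_for <- function(n) sprintf("S%03d", seq_len(n))

# Planted architecture: informative gene i is shifted in exactly one cluster
# (round-robin assignment), alternately hyper- (+delta) or hypo- (-delta)
# methylated there relative to its base level.
plant_gene_info <- function(cfg) {
  k <- length(cfg$n_per_cluster)
  genes <- gene_ids_for(cfg$n_genes)
  info_idx <- seq_len(cfg$n_informative)
  cluster <- rep(NA_integer_, cfg$n_genes)
  direction <- rep(0L, cfg$n_genes)
  cluster[info_idx] <- ((info_idx - 1L) %% k) + 1L
  direction[info_idx] <- ifelse((((info_idx - 1L) %/% k) %% 2L) == 0L, 1L, -1L)
  data.frame(gene = genes, informative = seq_len(cfg$n_genes) %in% info_idx,
             cluster = cluster, direction = direction,
             stringsAsFactors = FALSE)
}

#' Simulate a gene-by-sample methylation beta matrix with planted subtypes
#'
#' Values are drawn as Gaussians on the logit (M-value) scale around
#' cluster-specific means and mapped back through the inverse logit, so they
#' lie strictly in (0,1) and the M-value analysis of the planted effects is
#' exact. Informative genes have cluster means separated by `delta_beta` on
#' the beta scale; non-informative genes share one mean across clusters.
#'
#' @param config an [simulation_config()] object.
#' @return List with `beta` (matrix), `true_labels` (integer per sample),
#'   `informative_genes`, and the planted `gene_info` table.
#' @export
simulate_methylation <- function(config) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, "methylation"))
  k <- length(cfg$n_per_cluster)
  n <- sum(cfg$n_per_cluster)
  genes <- gene_ids_for(cfg$n_genes)
  samples <- sample_ids_for(n)
  labels <- rep(seq_len(k), cfg$n_per_cluster)
  info <- plant_gene_info(cfg)

  # promoter-like bimodal base levels: hypermethylating drivers start low and
  # gain delta_beta in their target cluster; hypomethylating drivers start
  # high and lose it; nuisance genes span the full range
  base <- runif(cfg$n_genes, 0.1, 0.9)
  base[info$direction == 1L] <- runif(sum(info$direction == 1L), 0.10, 0.20)
  base[info$direction == -1L] <- runif(sum(info$direction == -1L), 0.55, 0.80)
  # per-gene per-cluster mean on the beta scale, clamped inside (0,1)
  mu_beta <- matrix(base, nrow = cfg$n_genes, ncol = k)
  for (g in which(info$informative)) {
    mu_beta[g, info$cluster[g]] <- min(max(base[g] + info$direction[g] * cfg$delta_beta,
                                           0.02), 0.98)
  }
  mu_logit <- logit(mu_beta)
  beta <- matrix(0, cfg$n_genes, n, dimnames = list(genes, samples))
  for (cl in seq_len(k)) {
    idx <- which(labels == cl)
    beta[, idx] <- inv_logit(mu_logit[, cl] +
                               matrix(rnorm(cfg$n_genes * length(idx), 0, cfg$beta_noise_sd),
                                      cfg$n_genes, length(idx)))
  }
  names(labels) <- samples
  info$base <- base
  list(beta = beta, true_labels = labels,
       informative_genes = info$gene[info$informative], gene_info = info)
}

#' Simulate an adjacent-normal methylation matrix
#'
#' Normals share the tumor base level for non-informative genes; for
#' informative genes they sit half an effect size beyond the tumor base in
#' the direction opposite the driver's shift (hypermethylating drivers are
#' even lower in normal tissue, hypomethylating ones even higher), so the
#' tumor-vs-normal differential filter has a planted signal on exactly the
#' informative genes.
#'
#' @param config an [simulation_config()] object.
#' @param gene_info planted-architecture table from [simulate_methylation()]
#'   (must carry the `base` column).
#' @return Beta matrix (genes x `n_normal` samples, ids `N001`...).
#' @export
simulate_normal_methylation <- function(config, gene_info) {
  cfg <- config
  assert_that(!is.null(gene_info$base), "gene_info must carry base beta levels")
  set.seed(derive_seed(cfg$seed, "normals"))
  mu <- ifelse(gene_info$informative,
               pmin(pmax(gene_info$base - gene_info$direction * cfg$delta_beta / 2,
                         0.02), 0.98),
               gene_info$base)
  samples <- sprintf("N%03d", seq_len(cfg$n_normal))
  inv_logit(matrix(rnorm(cfg$n_genes * cfg$n_normal, 0, cfg$beta_noise_sd),
                   cfg$n_genes, cfg$n_normal,
                   dimnames = list(gene_info$gene, samples)) + logit(mu))
}

#' Simulate log-expression inversely coupled to driver-gene methylation
#'
#' Driver (informative) genes follow expression = intercept -
#' `expr_coupling` * beta + Gaussian noise; nuisance genes are intercept plus
#' noise. When a `purity` vector is supplied, each gene additionally receives
#' a random purity-confounding slope (sd `purity_effect`), emulating stromal
#' signal dilution that the purity correction of the drug module must remove.
#'
#' @param beta gene-by-sample beta matrix.
#' @param true_labels integer subtype per sample (used only for bookkeeping).
#' @param config an [simulation_config()] object.
#' @param gene_info planted-architecture table from [simulate_methylation()];
#'   when missing, all genes are treated as drivers.
#' @param purity optional per-sample purity in (0,1].
#' @return List with `expression` (matrix) and per-gene `intercepts`.
#' @export
simulate_expression <- function(beta, true_labels, config, gene_info = NULL,
                                purity = NULL) {
  cfg <- config
  check_beta_matrix(beta)
  if (!identical(names(true_labels), colnames(beta)))
    stop("alignment error: sample ids of labels and beta differ", call. = FALSE)
  if (!is.null(purity) && !identical(names(purity), colnames(beta)))
    stop("alignment error: sample ids of purity and beta differ", call. = FALSE)
  set.seed(derive_seed(cfg$seed, "expression"))
  p <- nrow(beta); n <- ncol(beta)
  driver <- if (is.null(gene_info)) rep(TRUE, p) else gene_info$informative
  intercepts <- runif(p, 4, 8)
  expr <- matrix(rnorm(p * n, 0, cfg$expr_noise_sd), p, n,
                 dimnames = dimnames(beta))
  expr <- expr + intercepts
  expr[driver, ] <- expr[driver, ] - cfg$expr_coupling * beta[driver, , drop = FALSE]
  if (!is.null(purity) && cfg$purity_effect > 0) {
    slopes <- rnorm(p, 0, cfg$purity_effect)
    expr <- expr + outer(slopes, purity)
  }
  list(expression = expr, intercepts = intercepts)
}

# analytic censoring probability for exponential event times with
# uniform(0, tmax) censoring, mixed over subtypes
censor_prob <- function(tmax, rates, weights) {
  sum(weights * (1 - exp(-rates * tmax)) / (rates * tmax))
}

#' Simulate subtype-dependent survival with uniform censoring
#'
#' Event times are exponential with hazard `baseline_hazard *
#' hazard_ratios[subtype]`; censoring is independent uniform on (0, T_max]
#' with T_max tuned by bisection so the expected censoring fraction hits
#' `censor_rate` within 2%.
#'
#' @param true_labels integer subtype per sample (named by sample id).
#' @param config an [simulation_config()] object.
#' @return data.frame with sample, time, event, true_label.
#' @export
simulate_survival <- function(true_labels, config) {
  cfg <- config
  assert_that(length(cfg$hazard_ratios) >= max(true_labels),
              "hazard_ratios needs one entry per subtype")
  set.seed(derive_seed(cfg$seed, "survival"))
  rates <- cfg$baseline_hazard * cfg$hazard_ratios[true_labels]
  t_event <- rexp(length(true_labels), rate = rates)
  if (cfg$censor_rate > 0) {
    w <- as.vector(table(factor(true_labels, seq_along(cfg$hazard_ratios))))
    w <- w / sum(w)
    rr <- cfg$baseline_hazard * cfg$hazard_ratios
    lo <- 1e-3; hi <- 1e6
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (censor_prob(mid, rr, w) > cfg$censor_rate) lo <- mid else hi <- mid
      if (abs(censor_prob(mid, rr, w) - cfg$censor_rate) < 1e-4) break
    }
    t_cens <- runif(length(true_labels), 0, mid)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, length(true_labels))
  }
  data.frame(sample = names(true_labels), time = time, event = event,
             true_label = as.integer(true_labels), stringsAsFactors = FALSE)
}

#' Simulate per-sample tumor purity
#'
#' Beta(5,2) across samples, truncated away from 0.
#' @param true_labels named subtype vector (defines sample ids).
#' @param config an [simulation_config()] object.
#' @return Named numeric vector in (0,1].
#' @export
simulate_purity <- function(true_labels, config) {
  set.seed(derive_seed(config$seed, "purity"))
  p <- pmax(stats::rbeta(length(true_labels), 5, 2), 0.05)
  names(p) <- names(true_labels)
  p
}

#' Simulate a cell-line pharmacogenomic panel
#'
#' Cell-line log-expression is Gaussian per gene; each drug's response is a
#' linear function (unit weights) of a disjoint expression signature plus
#' Gaussian noise, with the convention that LOWER response = more sensitive
#' tumors is applied downstream by construction of the transfer. Signature
#' membership is returned for recovery tests.
#'
#' @param config an [simulation_config()] object.
#' @param gene_ids optional gene id vector (defaults to the cohort's genes).
#' @param signatures optional named list of gene vectors, one per drug; when
#'   NULL, disjoint consecutive blocks of `drug_signature_size` genes.
#' @return List with `expression` (gene x line), `response` (long data.frame:
#'   line, drug, response), `signatures`.
#' @export
simulate_pharmacogenomics <- function(config, gene_ids = NULL, signatures = NULL) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, "pharmacogenomics"))
  if (is.null(gene_ids)) gene_ids <- gene_ids_for(cfg$n_genes)
  if (cfg$drug_signature_size > length(gene_ids))
    stop("invalid config: drug_signature_size exceeds gene count", call. = FALSE)
  if (is.null(signatures)) {
    if (cfg$n_drugs * cfg$drug_signature_size > length(gene_ids))
      stop("invalid config: disjoint signatures exceed the gene budget", call. = FALSE)
    signatures <- lapply(seq_len(cfg$n_drugs), function(d) {
      gene_ids[((d - 1) * cfg$drug_signature_size + 1):(d * cfg$drug_signature_size)]
    })
    names(signatures) <- sprintf("drug%02d", seq_len(cfg$n_drugs))
  }
  assert_that(all(unlist(signatures) %in% gene_ids), "signature genes outside gene ids")
  lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
  mu <- runif(length(gene_ids), 4, 8)
  expr <- matrix(rnorm(length(gene_ids) * cfg$n_cell_lines, 0, 1),
                 length(gene_ids), cfg$n_cell_lines,
                 dimnames = list(gene_ids, lines)) + mu
  resp <- do.call(rbind, lapply(names(signatures), function(d) {
    sig <- signatures[[d]]
    y <- 10 + colSums(expr[sig, , drop = FALSE] - mu[match(sig, gene_ids)]) +
      rnorm(cfg$n_cell_lines, 0, cfg$drug_noise_sd)
    data.frame(line = lines, drug = d, response = y, stringsAsFactors = FALSE)
  }))
  rownames(resp) <- NULL
  list(expression = expr, response = resp, signatures = signatures)
}

#' Simulate a complete synthetic cohort
#'
#' Composes methylation, purity, expression, survival, planted gene sets and a
#' matched cell-line pharmacogenomic panel. The last cluster is designated the
#' mesenchymal-shifted subtype and the first the epithelial one: the planted
#' "mesenchymal" expression signature is the set of genes hypomethylated (and
#' hence up-expressed) specifically in the last cluster, and symmetrically for
#' the epithelial signature. Each drug targets one subtype in rotation: its
#' response signature is that subtype's hypermethylated (down-expressed)
#' driver genes, so tumors of the target subtype score low (= sensitive).
#'
#' @param config an [simulation_config()] object.
#' @return List of class `emtsub_cohort`.
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  meth <- simulate_methylation(cfg)
  purity <- simulate_purity(meth$true_labels, cfg)
  expr <- simulate_expression(meth$beta, meth$true_labels, cfg,
                              gene_info = meth$gene_info, purity = purity)
  surv <- simulate_survival(meth$true_labels, cfg)
  k <- length(cfg$n_per_cluster)
  info <- meth$gene_info
  hypo <- function(cl) info$gene[info$informative & info$cluster == cl & info$direction == -1L]
  hyper <- function(cl) info$gene[info$informative & info$cluster == cl & info$direction == 1L]
  gene_sets <- c(list(epithelial = hypo(1L), mesenchymal = hypo(k)),
                 setNames(lapply(seq_len(k), hyper), sprintf("hyper_cluster%d", seq_len(k))),
                 setNames(lapply(seq_len(k), hypo), sprintf("hypo_cluster%d", seq_len(k))))
  gene_sets <- gene_sets[lengths(gene_sets) > 0]
  target_subtype <- ((seq_len(cfg$n_drugs) - 1L) %% k) + 1L
  signatures <- lapply(seq_len(cfg$n_drugs), function(d) {
    pool <- hyper(target_subtype[d])
    head(pool, min(length(pool), cfg$drug_signature_size))
  })
  names(signatures) <- sprintf("drug%02d", seq_len(cfg$n_drugs))
  names(target_subtype) <- names(signatures)
  pharm <- simulate_pharmacogenomics(cfg, gene_ids = rownames(meth$beta),
                                     signatures = signatures)
  beta_normal <- simulate_normal_methylation(cfg, meth$gene_info)
  # the EMT-associated annotation list: every informative gene plus half of
  # the noise genes, so the candidate gate's intersection is non-trivial
  set.seed(derive_seed(cfg$seed, "emtag"))
  noise_genes <- info$gene[!info$informative]
  emtag_list <- sort(c(meth$informative_genes,
                       sample(noise_genes, length(noise_genes) %/% 2)))
  out <- list(config = cfg, beta = meth$beta, beta_normal = beta_normal,
              emtag_list = emtag_list, expression = expr$expression,
              true_labels = meth$true_labels, survival = surv, purity = purity,
              informative_genes = meth$informative_genes, gene_info = info,
              gene_sets = gene_sets, cell_lines = pharm$expression,
              drug_response = pharm$response, drug_signatures = pharm$signatures,
              drug_target_subtype = target_subtype,
              mesenchymal_cluster = k, epithelial_cluster = 1L)
  class(out) <- "emtsub_cohort"
  out
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' @param cohort an `emtsub_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             beta_normal = file.path(dir, "beta_normal.tsv"),
             emtag = file.path(dir, "emtag_list.txt"),
             expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             gene_sets = file.path(dir, "planted_sets.gmt"),
             cell_lines = file.path(dir, "cell_line_expression.tsv"),
             drug_response = file.path(dir, "drug_response.tsv"),
             config = file.path(dir, "config.json"))
  write_matrix_tsv(cohort$beta, paths["beta"])
  write_matrix_tsv(cohort$beta_normal, paths["beta_normal"])
  writeLines(cohort$emtag_list, paths["emtag"])
  write_matrix_tsv(cohort$expression, paths["expression"])
  clin <- cohort$survival
  clin$purity <- cohort$purity[clin$sample]
  write_clinical_tsv(clin, paths["clinical"])
  write_gmt(cohort$gene_sets, paths["gene_sets"])
  write_matrix_tsv(cohort$cell_lines, paths["cell_lines"])
  write.table(cohort$drug_response, paths["drug_response"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  message("cohort written with master seed ", cohort$config$seed)
  invisible(paths)
}
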