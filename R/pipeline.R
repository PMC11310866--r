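#' Run the full synthetic subtyping pipeline
#'
#' Composes the stages end to end on a seeded synthetic cohort: simulate ->
#' tumor-vs-normal differential filter -> consensus-NMF subtyping with rank
#' selection -> EMT scoring and C1..Ck relabeling -> panel derivation and
#' classifier training -> drug-response transfer and nomination -> survival
#' comparison. Every stage writes plain-text outputs under `out_dir` and the
#' run manifest (config snapshot, master seed, md5 checksum per output) is
#' written last; replaying the same config reproduces byte-identical files.
#'
#' @param config an [simulation_config()]; its `seed` is the master seed.
#' @param out_dir output directory.
#' @param ranks candidate NMF ranks (default 2:5).
#' @param nmf_runs consensus restarts per rank (default 30).
#' @param qc_iter logistic-QC iterations (default 200).
#' @param stability_runs stability-selection runs (default 50).
#' @param stages character subset of
#'   c("dm_filter","subtype","emt","classifier","drug","survival") to run
#'   (default all; simulation always runs).
#' @return The manifest (list), invisibly written as manifest.json.
#' @export
run_pipeline <- function(config, out_dir, ranks = 2:5, nmf_runs = 30L,
                         qc_iter = 200L, stability_runs = 50L,
                         stages = c("dm_filter", "subtype", "emt",
                                    "classifier", "drug", "survival")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character(0)
  add_out <- function(path) outputs[[length(outputs) + 1]] <<- path

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE)
    })
  }

  cohort <- run_stage("simulate", function() simulate_cohort(config))
  for (p in write_cohort(cohort, file.path(out_dir, "inputs"))) add_out(p)

  candidates <- rownames(cohort$beta)
  if ("dm_filter" %in% stages) {
    run_stage("dm_filter", function() {
      combined <- cbind(cohort$beta_normal, cohort$beta)
      grp <- factor(rep(c("normal", "tumor"),
                        c(ncol(cohort$beta_normal), ncol(cohort$beta))),
                    levels = c("normal", "tumor"))
      dm <- moderated_t(combined, grp)
      candidates <<- select_candidates(dm, cohort$emtag_list)
      write.table(dm, file.path(out_dir, "dm_table.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      writeLines(candidates, file.path(out_dir, "candidate_genes.txt"))
      add_out(file.path(out_dir, "dm_table.tsv"))
      add_out(file.path(out_dir, "candidate_genes.txt"))
    })
  }

  subtype_labels <- NULL; model <- NULL
  if ("subtype" %in% stages) {
    run_stage("subtype", function() {
      rk <- select_rank(cohort$beta[candidates, , drop = FALSE], ranks = ranks,
                        n_runs = nmf_runs, seed = derive_seed(seed, "nmf"))
      model <<- rk$models[[paste0("k", rk$chosen_rank)]]
      subtype_labels <<- model$labels
      write.table(rk$table, file.path(out_dir, "rank_report.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_matrix_tsv(model$consensus, file.path(out_dir, "consensus.tsv"),
                       id_col = "sample")
      add_out(file.path(out_dir, "rank_report.tsv"))
      add_out(file.path(out_dir, "consensus.tsv"))
    })
  }

  labels_named <- NULL
  if ("emt" %in% stages && !is.null(subtype_labels)) {
    run_stage("emt", function() {
      es <- cohort$gene_sets$epithelial; ms <- cohort$gene_sets$mesenchymal
      scores <- data.frame(
        sample = colnames(cohort$expression),
        ks = score_ks(cohort$expression, es, ms),
        gs76 = as.vector(score_76gs(cohort$expression, c(es, ms), es[1])),
        mlr = score_mlr(cohort$expression, es, ms))
      rel <- relabel_by_emt(subtype_labels, scores$mlr)
      labels_named <<- rel$labels
      scores$subtype <- as.character(labels_named)
      write.table(scores, file.path(out_dir, "emt_scores.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(rel$mapping, file.path(out_dir, "subtype_mapping.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      add_out(file.path(out_dir, "emt_scores.tsv"))
      add_out(file.path(out_dir, "subtype_mapping.tsv"))
    })
  }
  if (is.null(labels_named) && !is.null(subtype_labels))
    labels_named <- factor(paste0("C", subtype_labels))

  classifier <- NULL
  if ("classifier" %in% stages && !is.null(labels_named)) {
    run_stage("classifier", function() {
      trace <- derive_panel(cohort$expression, labels_named,
                            seed = derive_seed(seed, "panel"),
                            qc_iter = qc_iter, stability_runs = stability_runs)
      comp <- model_competition(cohort$expression[trace$panel_genes, , drop = FALSE],
                                labels_named, seed = derive_seed(seed, "compete"))
      classifier <<- train_final(cohort$expression[trace$panel_genes, , drop = FALSE],
                                 labels_named, family = comp$winner,
                                 seed = derive_seed(seed, "final"),
                                 cv_metrics = comp$metrics)
      jsonlite::write_json(list(panel = trace$panel_genes,
                                frequency = as.list(trace$selection_frequency),
                                stages = list(
                                  consensus_da = trace$consensus_da_genes,
                                  leaf = trace$leaf_genes,
                                  post_correlation = trace$post_correlation_genes,
                                  wrapper = trace$wrapper_genes),
                                winner = comp$winner),
                           file.path(out_dir, "panel_trace.json"),
                           auto_unbox = TRUE, digits = NA)
      write.table(comp$summary, file.path(out_dir, "model_metrics.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      add_out(file.path(out_dir, "panel_trace.json"))
      add_out(file.path(out_dir, "model_metrics.tsv"))
    })
  }

  if ("drug" %in% stages && !is.null(labels_named)) {
    run_stage("drug", function() {
      corrected <- purity_correct(cohort$expression, cohort$purity)
      transfer <- ridge_transfer(cohort$cell_lines, cohort$drug_response,
                                 corrected, seed = derive_seed(seed, "ridge"))
      nom <- nominate_subtype_drugs(transfer$predictions, labels_named)
      write.table(nom$table, file.path(out_dir, "drug_nominations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_matrix_tsv(nom$normalized, file.path(out_dir, "drug_scores.tsv"),
                       id_col = "drug")
      add_out(file.path(out_dir, "drug_nominations.tsv"))
      add_out(file.path(out_dir, "drug_scores.tsv"))
    })
  }

  if ("survival" %in% stages && !is.null(labels_named)) {
    run_stage("survival", function() {
      lr <- logrank_test(cohort$survival, labels_named)
      df <- data.frame(chisq = lr$chisq, df = lr$df, p = lr$p,
                       stars = signif_stars(lr$p))
      write.table(df, file.path(out_dir, "survival_logrank.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      add_out(file.path(out_dir, "survival_logrank.tsv"))
    })
  }

  outputs <- unlist(outputs)
  manifest <- list(config = unclass(config), master_seed = seed,
                   stages = stages, package_version = "0.1.0",
                   outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                                              basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
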