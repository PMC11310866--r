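#!/usr/bin/env Rscript
# Stage 1 - generate the synthetic study cohort.
#
# Writes the full synthetic cohort (tumor + adjacent-normal methylation,
# coupled expression, clinical table, planted gene sets, cell-line
# pharmacogenomics) under results/cohort/. The defaults are the study
# conditions used throughout: three balanced subtypes of 40 samples, 300
# genes with 60 planted drivers (delta-beta 0.25), ~30% censoring, and five
# drugs whose response signatures are the hypermethylated drivers of one
# subtype each.

library(emtsub)

seed <- 20260929L
cfg <- simulation_config(seed = seed)
cohort <- simulate_cohort(cfg)
paths <- write_cohort(cohort, "results/cohort")

message(sprintf("cohort: %d tumors (%s), %d normals, %d genes (%d informative)",
                ncol(cohort$beta),
                paste(table(cohort$true_labels), collapse = "/"),
                ncol(cohort$beta_normal), nrow(cohort$beta),
                length(cohort$informative_genes)))
message(sprintf("censoring: %.0f%%; drugs: %d x %d cell lines",
                100 * mean(1 - cohort$survival$event),
                length(cohort$drug_signatures), ncol(cohort$cell_lines)))
message("inputs written under results/cohort/")
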