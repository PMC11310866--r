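#!/usr/bin/env Rscript
# Stage 6 - purity correction, ridge transfer, and drug nomination.
#
# Tumor expression is purified by per-gene linear purity regression, each
# drug's ridge model (10-fold CV over the penalty grid) is trained on the
# cell-line panel and applied to the purified tumors, and drugs are assigned
# to the subtype they are differentially predicted to work in
# (Kruskal-Wallis + BH over drugs, best-vs-runner-up gap >= 0.5 pooled SD).

library(emtsub)

seed <- 20260929L
expr <- read_matrix_tsv("results/cohort/expression.tsv")
clin <- read_clinical_tsv("results/cohort/clinical.tsv")
purity <- setNames(clin$purity, clin$sample)[colnames(expr)]
cells <- read_matrix_tsv("results/cohort/cell_line_expression.tsv")
resp <- read.table("results/cohort/drug_response.tsv", header = TRUE,
                   stringsAsFactors = FALSE)
scores <- read.table("results/emt_scores.tsv", header = TRUE)
labels <- setNames(scores$subtype, scores$sample)[colnames(expr)]

corrected <- purity_correct(expr, purity)
transfer <- ridge_transfer(cells, resp, corrected,
                           seed = derive_seed(seed, "ridge"))
message("per-drug training CV correlation:")
print(transfer$per_drug, digits = 3)

nom <- nominate_subtype_drugs(transfer$predictions, labels)
write.table(nom$table, "results/drug_nominations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_matrix_tsv(nom$normalized, "results/drug_scores.tsv", id_col = "drug")

message("nominations (lower predicted response = more sensitive):")
print(nom$table[, c("drug", "q", "subtype", "gap_sd", "nominated")], digits = 3)
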