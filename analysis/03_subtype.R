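#!/usr/bin/env Rscript
# Stage 3 - consensus-NMF subtype discovery with rank selection.
#
# Brunet KL-NMF on the candidate beta matrix, 30 seeded restarts per rank
# over ranks 2-6; rank chosen by the steepest forward drop of the
# cophenetic x dispersion combined score.

library(emtsub)

seed <- 20260929L
beta <- read_matrix_tsv("results/cohort/beta.tsv")
candidates <- readLines("results/candidate_genes.txt")

rk <- select_rank(beta[candidates, , drop = FALSE], ranks = 2:6,
                  n_runs = 30L, seed = derive_seed(seed, "nmf"))
model <- rk$models[[paste0("k", rk$chosen_rank)]]

write.table(rk$table, "results/rank_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_matrix_tsv(model$consensus, "results/consensus.tsv", id_col = "sample")
write.table(data.frame(sample = names(model$labels), cluster = model$labels),
            "results/subtype_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("rank table:")
print(round(rk$table, 3))
message(sprintf("chosen rank: %d (low confidence: %s); mean silhouette %.2f; cluster sizes %s",
                rk$chosen_rank, rk$low_confidence, model$silhouette_mean,
                paste(table(model$labels), collapse = "/")))
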