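#!/usr/bin/env Rscript
# Stage 7 - survival comparison of the discovered subtypes.

library(emtsub)

clin <- read_clinical_tsv("results/cohort/clinical.tsv")
scores <- read.table("results/emt_scores.tsv", header = TRUE)
labels <- setNames(scores$subtype, scores$sample)[clin$sample]

lr <- logrank_test(clin, labels)
out <- data.frame(chisq = lr$chisq, df = lr$df, p = lr$p,
                  stars = signif_stars(lr$p), n_events = lr$n_events)
write.table(out, "results/survival_logrank.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

km <- survival::survfit(survival::Surv(clin$time, clin$event) ~ labels)
message("median survival by subtype:")
print(summary(km)$table[, c("records", "events", "median")])
message(sprintf("log-rank chi-square %.2f on %d df, p = %.3g %s",
                lr$chisq, lr$df, lr$p, signif_stars(lr$p)))
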