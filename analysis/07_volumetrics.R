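#!/usr/bin/env Rscript
# Stage 7: volumetric comparison and age associations.
#
# Per-node ANCOVA (group effect adjusted for sex, age, ICV) with BH-FDR
# across nodes, and Spearman correlations of each node volume with age.

suppressMessages(library(thalnet))

cohort <- read_cohort("results/cohort.tsv")
anc <- ancova_compare(cohort, reference = "HC")
write_ancova_table(anc, "results/volumetrics.tsv")
cat("ANCOVA group effects (uncorrected p < 0.05):",
    sum(anc$p < 0.05), "of", nrow(anc), "nodes;",
    sum(anc$fdr_significant), "survive FDR\n")

sp <- spearman_table(cohort, "age")
utils::write.table(sp, "results/spearman_age.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("strongest age association:",
    sp$roi[which.max(abs(sp$rho))],
    sprintf("(rho = %.2f)\n", sp$rho[which.max(abs(sp$rho))]))
cat("wrote results/volumetrics.tsv, results/spearman_age.tsv\n")
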