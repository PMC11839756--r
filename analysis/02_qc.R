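#!/usr/bin/env Rscript
# Stage 2: statistical quality control.
#
# Tukey-fence outlier screening of every node volume (Q1 - 1.5 IQR,
# Q3 + 1.5 IQR; type-7 quartiles). Flags are reported, never auto-dropped:
# in practice they would inform visual review of the segmentations.

suppressMessages(library(thalnet))

cohort <- read_cohort("results/cohort.tsv")
qc <- qc_report(cohort)
print(qc)
write_qc_report(qc, "results")
cat("flag rate:",
    round(qc$summary["n_outlier_flags"] /
            (nrow(cohort) * qc$summary["n_rois"]), 4), "\n")
cat("wrote results/qc_outliers.tsv, results/qc_summary.json\n")
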