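#!/usr/bin/env Rscript
# Stage 3: covariate adjustment.
#
# Every node volume is residualized on age, sex and intracranial volume by
# pooled OLS, so the networks built next are partial-correlation networks
# given those confounds.

suppressMessages(library(thalnet))

cohort <- read_cohort("results/cohort.tsv")
model <- fit_adjustment(cohort)
adjusted <- residualize(cohort, model)
write_adjustment_model(model, "results/adjustment_model.tsv")
write_cohort(adjusted, "results/adjusted_cohort.tsv")

# residual means per ROI are zero by construction
stopifnot(max(abs(colMeans(
  as.matrix(as.data.frame(adjusted)[, volume_cols(adjusted)])))) < 1e-8)
cat("wrote results/adjustment_model.tsv, results/adjusted_cohort.tsv\n")
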