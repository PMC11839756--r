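#!/usr/bin/env Rscript
# Stage 4: group structural covariance networks.
#
# One 22-node weighted undirected network per group: edges are Pearson
# correlations of the adjusted volumes across the group's subjects, with
# negative correlations set to zero.

suppressMessages(library(thalnet))

adjusted <- read_cohort("results/adjusted_cohort.tsv", adjusted = TRUE)
for (g in c("ET", "HC")) {
  net <- build_group_network(adjusted, g)
  print(net)
  export_network(net, sprintf("results/network_%s.tsv", g),
                 sprintf("results/edges_%s.tsv", g))
}
cat("wrote results/network_{ET,HC}.tsv and edge lists\n")
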