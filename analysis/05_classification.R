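#!/usr/bin/env Rscript
# Step 5 — classify indicators by environmental responsiveness.
#
# Pairwise Euclidean distances between the flattened mutual-prediction
# matrices, Ward (D2) clustering, and SIMPROF permutation tests at
# alpha = 0.01 to keep only statistically supported splits. Indicators in
# one significant cluster responded to the environmental history of the
# series in the same way.

library(biodivedm)

matrices <- readRDS("results/mutual/matrices.rds")

res <- classify_indicators(matrices, alpha = 0.01, n_perm = 999, seed = 1)
print(res)

write_cluster_table(res, "results/clusters.csv")
write_dendrogram(res$hclust, "results/dendrogram.nwk")
dm <- as.matrix(res$dist)
write.csv(cbind(indicator = rownames(dm), as.data.frame(dm)),
          "results/distances.csv", row.names = FALSE)

cat("\nnode p-values (NA = untestable or untested):\n")
print(res$node_p)
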