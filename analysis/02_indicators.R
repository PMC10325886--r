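#!/usr/bin/env Rscript
# Step 2 — the ten biodiversity indicators per survey.
#
# Reads the community and species tables from step 1 and computes, for each
# survey: richness S, total abundance N, dominance p_max, Simpson D, Shannon
# H', the three evenness indices (E_D, E_H, E_var), Warwick-Clarke taxonomic
# diversity delta, and the community mean of standardized COD latitude.

library(biodivedm)

community <- read_community("results/data/community.csv")
species <- read_species("results/data/species.csv")

ind <- indicator_time_series(community, species)
dir.create("results", showWarnings = FALSE)
write_indicators(ind, "results/indicators.csv")

cat("indicator table:", nrow(ind), "surveys x", ncol(ind) - 1, "indicators\n")
print(round(sapply(ind[indicator_names()], function(x)
  c(min = min(x), median = median(x), max = max(x))), 3))
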