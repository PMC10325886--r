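#!/usr/bin/env Rscript
# Step 1 — generate the study community.
#
# Simulates the default synthetic analogue of the monitoring data: 95 species
# over 88 monthly surveys, seasonal temperature forcing with a +2 degC shift
# in the mean after survey 44 (the warming analogue), Poisson-observed
# counts. Writes the abundance table and species metadata that every later
# step reads.

library(biodivedm)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- community_sim(simulation_config(seed = 1))
write_community(sim$community, file.path(out, "community.csv"))
write_species(sim$species, file.path(out, "species.csv"))
write.csv(data.frame(survey = seq_along(sim$temperature),
                     temperature = sim$temperature),
          file.path(out, "temperature.csv"), row.names = FALSE)

cat("surveys:", nrow(sim$community$abundance),
    " species:", ncol(sim$community$abundance), "\n")
cat("species with >=1 zero survey:",
    sum(apply(sim$community$abundance, 2, function(s) any(s == 0))), "\n")
cat("written to", out, "\n")
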