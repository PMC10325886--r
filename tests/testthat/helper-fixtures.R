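# three-species taxonomic fixture: sp1/sp2 share a family (not genus),
# sp3 sits in a different order
tax3 <- function() {
  data.frame(species = c("sp1", "sp2", "sp3"),
             genus = c("g1", "g2", "g3"),
             family = c("f1", "f1", "f2"),
             order = c("o1", "o1", "o2"),
             cod_latitude = c(10, 20, 60),
             stringsAsFactors = FALSE)
}

# small community for io / pipeline tests
tiny_sim <- function(n_species = 20, n_time = 45, seed = 7) {
  community_sim(simulation_config(n_species = n_species, n_time = n_time,
                                  change_index = round(n_time / 2),
                                  seed = seed))
}
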