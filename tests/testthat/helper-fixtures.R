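# Shared fixtures: small seeded datasets and noise-free generating models.

default_dataset <- function(seed = 1L, n_per_group = c(8L, 8L),
                            scm = scm_params()) {
  simulate_dataset(build_design(design_config(n_per_group = n_per_group,
                                              seed = seed)),
                   scm, seed = seed)
}

noiseless_scm <- function(...) {
  args <- list(...)
  base <- scm_params()
  base$gene1$noise_sd <- 0
  base$gene2$noise_sd <- 0
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  class(base) <- "scm_params"
  base
}

# SCM with the cross-gene structural edge enabled: gene-2 responds strongly
# to Eomesa and feeds into gene-1, so the naive difference in means for the
# beta-catenin contrast is confounded through the shared embryo.
confounded_scm <- function(weight = 0.8) {
  scm_params(cross_gene_weight = weight)
}

ndr1_estimand <- function(data) {
  screen <- variable_screen(treatments = c("bcatenin", "smad2", "time"),
                            common_causes = "eomesa", gene = "ndr1")
  identify_backdoor(build_causal_graph(screen, "ndr1"), data)
}
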