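# Stage 1: generate the synthetic multi-species two-caste dataset.
#
# 16 species on an ultrametric pure-birth tree, 2 castes x 3 replicates,
# 2000 orthologous gene groups with 10 planted co-expression modules,
# binary species traits evolved on the tree, orthology dropout and
# transcript multiplicity. Everything downstream reads these files.

source("analysis/00_common.R")

cfg <- sim_config(seed = SEED)
tree <- simulate_tree(cfg$n_species, seed = SEED + 101)
traits <- simulate_species_traits(tree, cfg$trait_switch_rate,
                                  seed = SEED + 211)
sim <- simulate_expression(cfg, tree, traits)

dir <- res_path("data")
write_simulation(sim, tree, traits, dir)

cat("Simulated", nrow(sim$counts), "transcripts (",
    length(unique(sim$ogg_map$ogg)), "OGGs ) x", ncol(sim$counts),
    "samples for", cfg$n_species, "species\n")
cat("Planted", cfg$n_modules, "modules covering",
    sum(sim$truth$module > 0), "OGGs; trait prevalences:",
    paste(colMeans(traits[, -1]), collapse = " "), "\n")
cat("Outputs in", dir, "\n")
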