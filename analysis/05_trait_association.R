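# Stage 5: associate module eigengenes with caste and species traits.
#
# One Bayesian phylogenetic mixed model per module eigengene: caste and
# the three binary species traits as fixed effects, a species random
# effect with Brownian covariance from the tree, inverse-Gamma(0.01, 0.01)
# variance priors, Gibbs sampling at desk scale (50,000 iterations,
# 15,000 burn-in, thinning 10).

source("analysis/00_common.R")

eg <- read_counts_matrix(res_path("network", "eigengenes.tsv"))
tree <- ape::read.tree(res_path("data", "tree.nwk"))
traits <- read_tsv(res_path("data", "traits.tsv"))
samples <- read_tsv(res_path("data", "samples.tsv"))

C <- phylo_covariance(tree)
samples <- samples[match(colnames(eg), samples$sample), ]
design <- data.frame(
  caste = samples$caste,
  traits[match(samples$species, traits$species),
         c("worker_sterility", "queen_number", "invasiveness")],
  species = samples$species)

fits <- lapply(seq_len(nrow(eg)), function(i)
  fit_phylo_mixed_model(eg[i, ], design, C, seed = SEED + 809 + i))
names(fits) <- rownames(eg)
labels <- classify_modules(fits, alpha = 0.05)

assoc <- do.call(rbind, lapply(names(fits), function(m)
  data.frame(module = m, fits[[m]]$summary)))
write_tsv(assoc, res_path("association", "association.tsv"))
write_tsv(labels, res_path("association", "module_labels.tsv"))

cat(sum(labels$caste != "NTA"), "of", nrow(labels),
    "module eigengenes are caste-associated ( queen",
    sum(labels$caste == "queen"), ", worker",
    sum(labels$caste == "worker"), ")\n")
for (tcol in c("worker_sterility", "queen_number", "invasiveness"))
  cat(tcol, ":", sum(labels[[tcol]] != "NTA"), "associated modules\n")
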