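# Shared fixtures, built in code at test time.

# Small species tree + traits + design shared by association tests.
make_design <- function(n_species = 16, n_rep = 3, tree_seed = 1,
                        trait_seed = 2) {
  tree <- simulate_tree(n_species, tree_seed)
  traits <- simulate_species_traits(tree, 1, trait_seed)
  samples <- expand.grid(rep = seq_len(n_rep), caste = c("queen", "worker"),
                         species = tree$tip.label,
                         stringsAsFactors = FALSE)
  design <- data.frame(
    caste = samples$caste,
    traits[match(samples$species, traits$species),
           c("worker_sterility", "queen_number", "invasiveness")],
    species = samples$species)
  list(tree = tree, traits = traits, design = design,
       C = phylo_covariance(tree))
}

# Expression matrix with b planted blocks (within-block correlation rho)
# plus optional pure-noise genes.
planted_blocks <- function(n_per_block = 40, n_blocks = 3, n_samples = 60,
                           rho = 0.9, n_noise = 0, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n_blocks * n_samples), n_blocks, n_samples)
  x <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
    sqrt(rho) * f[rep(b, n_per_block), , drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n_per_block * n_samples), n_per_block)))
  if (n_noise > 0)
    x <- rbind(x, matrix(rnorm(n_noise * n_samples), n_noise))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  truth <- c(rep(seq_len(n_blocks), each = n_per_block),
             rep(0, n_noise))
  list(x = x, truth = truth)
}

# NB count matrix for a two-caste comparison; `signal` rows get `fold`-times
# higher means in the caste given by their sign (+ queen, - worker).
nb_caste_counts <- function(n_genes, n_per_caste, phi = 0.1,
                            signal = integer(0), fold = 4, seed = 1) {
  set.seed(seed)
  grp <- rep(c("queen", "worker"), each = n_per_caste)
  mu <- exp(rnorm(n_genes, 4, 1))
  y <- matrix(rnbinom(n_genes * 2 * n_per_caste,
                      mu = rep(mu, 2 * n_per_caste), size = 1 / phi),
              n_genes, 2 * n_per_caste,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(2 * n_per_caste))))
  up <- signal[signal > 0]; dn <- -signal[signal < 0]
  if (length(up))
    y[up, grp == "queen"] <- rnbinom(length(up) * n_per_caste,
                                     mu = rep(mu[up] * fold, n_per_caste),
                                     size = 1 / phi)
  if (length(dn))
    y[dn, grp == "worker"] <- rnbinom(length(dn) * n_per_caste,
                                      mu = rep(mu[dn] * fold, n_per_caste),
                                      size = 1 / phi)
  list(counts = y, groups = grp, mu = mu)
}

# Minimal DE table in the shape caste_de_test() returns.
fake_de_table <- function(genes, sig_genes, direction = "queen") {
  data.frame(gene = genes,
             logFC = ifelse(genes %in% sig_genes,
                            ifelse(direction == "queen", 2, -2), 0),
             p = ifelse(genes %in% sig_genes, 1e-4, 0.6),
             q = ifelse(genes %in% sig_genes, 1e-3, 0.8),
             direction = ifelse(genes %in% sig_genes, direction, "ns"),
             untestable = FALSE)
}
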