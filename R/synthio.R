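#' Simulation configuration for synthetic multi-species caste datasets
#'
#' Bundles and validates all parameters of the synthetic-data generator.
#' Defaults describe the study design the package targets: 16 species on an
#' ultrametric phylogeny, two female castes (queen/worker) with three
#' biological replicates each, a few thousand orthologous gene groups (OGGs)
#' of which a minority belong to planted co-expression modules driven by
#' caste, species-level binary traits, and phylogenetically structured
#' species effects.
#'
#' @param n_species number of species (tree tips).
#' @param n_replicates biological replicates per caste per species.
#' @param n_oggs number of orthologous gene groups.
#' @param n_modules number of planted co-expression modules.
#' @param module_size_range integer pair; module sizes are drawn uniformly
#'   from this range.
#' @param caste_effect_sd sd of the per-module caste effect on the latent
#'   module factor (log-expression scale).
#' @param trait_effect_sd sd of per-module species-trait effects.
#' @param phylo_sd Brownian-motion rate for species effects on module
#'   factors; species effects are drawn from N(0, phylo_sd^2 * C) with C the
#'   phylogenetic correlation matrix.
#' @param factor_noise_sd sd of iid sample-level noise on module factors.
#' @param loading multiplier from module factor to member-gene log-mean;
#'   background genes have loading 0.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters for
#'   per-gene baseline mean counts.
#' @param nb_dispersion_shape,nb_dispersion_scale gamma prior on per-gene NB
#'   dispersion phi (Var = mu + phi * mu^2).
#' @param libsize_log_mean,libsize_log_sd log-normal parameters for relative
#'   library sizes.
#' @param dropout_prob probability that an OGG is absent (orthology dropout)
#'   in a given species; all samples of that species become missing.
#' @param multi_transcript_frac fraction of OGGs represented by 2-3
#'   transcripts instead of one (exercises transcript aggregation).
#' @param trait_switch_rate transition rate of the symmetric two-state
#'   Markov chain used to evolve binary traits along the tree (per unit
#'   branch length).
#' @param omega_coeffs named numeric vector of length 6 giving the
#'   generating model for log dN/dS: intercept, log-expression slope,
#'   log-connectivity slope, caste-association main effect, and the
#'   connectivity-by-caste and expression-by-caste interactions.
#' @param omega_log_sd sd of Gaussian noise on log dN/dS.
#' @param seed master seed; per-stage streams are derived from it by fixed
#'   offsets.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 16L,
                       n_replicates = 3L,
                       n_oggs = 2000L,
                       n_modules = 10L,
                       module_size_range = c(30L, 100L),
                       caste_effect_sd = 1,
                       trait_effect_sd = 0.5,
                       phylo_sd = 0.5,
                       factor_noise_sd = 0.3,
                       loading = 1,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1,
                       nb_dispersion_shape = 2,
                       nb_dispersion_scale = 0.05,
                       libsize_log_mean = 0,
                       libsize_log_sd = 0.1,
                       dropout_prob = 0.05,
                       multi_transcript_frac = 0.1,
                       trait_switch_rate = 1,
                       omega_coeffs = c(intercept = -1, expr = -0.2,
                                        conn = -0.3, caste = 0.3,
                                        conn_caste = 0.2, expr_caste = -0.1),
                       omega_log_sd = 0.5,
                       seed = 1L) {
  check_scalar(n_species, "n_species", min = 2, integer = TRUE)
  check_scalar(n_replicates, "n_replicates", min = 1, integer = TRUE)
  check_scalar(n_oggs, "n_oggs", min = 1, integer = TRUE)
  check_scalar(n_modules, "n_modules", min = 0, integer = TRUE)
  if (length(module_size_range) != 2 ||
      module_size_range[1] > module_size_range[2] ||
      any(module_size_range < 1))
    stop("module_size_range must be an increasing pair of positive integers")
  if (n_modules * module_size_range[2] > n_oggs)
    stop("planted modules cannot exceed n_oggs genes in total")
  for (nm in c("caste_effect_sd", "trait_effect_sd", "phylo_sd",
               "factor_noise_sd", "baseline_log_sd", "nb_dispersion_shape",
               "nb_dispersion_scale", "libsize_log_sd", "trait_switch_rate",
               "omega_log_sd"))
    check_scalar(get(nm), nm, min = 0)
  check_scalar(dropout_prob, "dropout_prob", min = 0, max = 1)
  check_scalar(multi_transcript_frac, "multi_transcript_frac",
               min = 0, max = 1)
  if (length(omega_coeffs) != 6) stop("omega_coeffs must have length 6")
  cfg <- list(n_species = as.integer(n_species),
              n_replicates = as.integer(n_replicates),
              n_oggs = as.integer(n_oggs),
              n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              caste_effect_sd = caste_effect_sd,
              trait_effect_sd = trait_effect_sd,
              phylo_sd = phylo_sd,
              factor_noise_sd = factor_noise_sd,
              loading = loading,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              nb_dispersion_shape = nb_dispersion_shape,
              nb_dispersion_scale = nb_dispersion_scale,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              dropout_prob = dropout_prob,
              multi_transcript_frac = multi_transcript_frac,
              trait_switch_rate = trait_switch_rate,
              omega_coeffs = omega_coeffs,
              omega_log_sd = omega_log_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an ultrametric pure-birth species tree
#'
#' Pure-birth (Yule) tree rescaled to total height 1, so root-to-tip path
#' lengths are all exactly 1. Deterministic given the seed.
#'
#' @param n_species number of tips (>= 2).
#' @param seed RNG seed.
#' @return an [ape::phylo] tree with tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  check_scalar(n_species, "n_species", min = 2, integer = TRUE)
  tree <- local_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(n_species)])
  tree$edge.length <- tree$edge.length / height
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Evolve binary species traits on a tree
#'
#' Each trait (worker sterility, queen number, invasiveness) evolves
#' independently under a symmetric two-state Markov chain with the given
#' switch rate, from a Bernoulli(0.5) root state. The flip probability along
#' a branch of length t is (1 - exp(-2 * rate * t)) / 2.
#'
#' @param tree ultrametric [ape::phylo] tree.
#' @param switch_rate non-negative transition rate per unit branch length.
#' @param seed RNG seed.
#' @return data.frame with columns species, worker_sterility, queen_number,
#'   invasiveness (0/1), one row per tip in tip order.
#' @export
simulate_species_traits <- function(tree, switch_rate = 1, seed = 1L) {
  check_scalar(switch_rate, "switch_rate", min = 0)
  n_tip <- length(tree$tip.label)
  traits <- c("worker_sterility", "queen_number", "invasiveness")
  out <- local_seed(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")
    vapply(traits, function(dummy) {
      state <- integer(n_tip + tr$Nnode)
      root <- n_tip + 1L
      state[root] <- rbinom(1, 1, 0.5)
      for (e in seq_len(nrow(tr$edge))) {
        parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
        p_flip <- (1 - exp(-2 * switch_rate * tr$edge.length[e])) / 2
        flip <- rbinom(1, 1, p_flip)
        state[child] <- if (flip) 1L - state[parent] else state[parent]
      }
      state[seq_len(n_tip)]
    }, integer(n_tip))
  })
  data.frame(species = tree$tip.label, out, row.names = NULL)
}

#' Simulate a multi-species two-caste expression dataset with planted modules
#'
#' Generates a transcript-by-sample negative-binomial count matrix whose
#' co-expression structure, caste and trait effects, and phylogenetic signal
#' follow the generative model: each planted module m has a latent factor
#' per sample composed of a caste effect, species-trait effects, a Brownian
#' species effect with covariance `phylo_sd^2 * C` (C from the tree), and
#' iid noise; member genes' log-means move with the factor through
#' `loading`; counts are NB with gamma-distributed per-gene dispersions and
#' log-normal library sizes. Orthology dropout blanks an OGG in all samples
#' of a species; a fraction of OGGs appear as 2-3 transcripts to exercise
#' aggregation.
#'
#' @param config a [sim_config()].
#' @param tree species tree; tips must match the trait table.
#' @param traits data.frame from [simulate_species_traits()].
#' @return list with elements `counts` (integer matrix, transcripts x
#'   samples, NA = missing), `samples` (sample metadata), `ogg_map`
#'   (transcript -> OGG), and `truth` (planted module labels and effects).
#' @export
simulate_expression <- function(config, tree, traits) {
  stopifnot(inherits(config, "sim_config"))
  if (!setequal(tree$tip.label, traits$species))
    stop("tree tips and trait table species do not match")
  traits <- traits[match(tree$tip.label, traits$species), ]
  n_sp <- config$n_species
  if (length(tree$tip.label) != n_sp)
    stop("tree has ", length(tree$tip.label), " tips but config expects ",
         n_sp, " species")

  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         caste = c("queen", "worker"),
                         species = tree$tip.label,
                         stringsAsFactors = FALSE)[, 3:1]
  samples$sample <- sprintf("%s_%s_r%d", samples$species,
                            substr(samples$caste, 1, 1), samples$replicate)
  n_samp <- nrow(samples)

  local_seed(stage_seed(config$seed, "expression"), {
    # planted module membership
    ogg_ids <- sprintf("OGG%05d", seq_len(config$n_oggs))
    sizes <- if (config$n_modules > 0)
      sample(seq(config$module_size_range[1], config$module_size_range[2]),
             config$n_modules, replace = TRUE) else integer(0)
    module <- integer(config$n_oggs)
    if (config$n_modules > 0) {
      picked <- sample.int(config$n_oggs, sum(sizes))
      module[picked] <- rep(seq_len(config$n_modules), times = sizes)
    }

    # latent module factors: caste + traits + Brownian species effect + noise
    caste01 <- as.numeric(samples$caste == "queen")
    trait_mat <- as.matrix(traits[, c("worker_sterility", "queen_number",
                                      "invasiveness")])
    trait_by_sample <- trait_mat[match(samples$species, traits$species), ,
                                 drop = FALSE]
    C <- phylo_covariance(tree)
    beta_caste <- rnorm(config$n_modules, 0, config$caste_effect_sd)
    beta_trait <- matrix(rnorm(config$n_modules * 3, 0,
                               config$trait_effect_sd),
                         nrow = config$n_modules)
    u_species <- if (config$phylo_sd > 0 && config$n_modules > 0) {
      L <- chol(C + diag(1e-10, n_sp))
      matrix(rnorm(config$n_modules * n_sp), config$n_modules) %*%
        (config$phylo_sd * L)
    } else matrix(0, max(config$n_modules, 1), n_sp)
    colnames(u_species) <- tree$tip.label

    factors <- matrix(0, max(config$n_modules, 1), n_samp)
    for (m in seq_len(config$n_modules)) {
      factors[m, ] <- beta_caste[m] * (caste01 - 0.5) +
        drop((trait_by_sample - 0.5) %*% beta_trait[m, ]) +
        u_species[m, samples$species] +
        rnorm(n_samp, 0, config$factor_noise_sd)
    }

    # per-gene baseline, dispersion, loading
    baseline <- exp(rnorm(config$n_oggs, config$baseline_log_mean,
                          config$baseline_log_sd))
    phi <- rgamma(config$n_oggs, shape = config$nb_dispersion_shape,
                  scale = config$nb_dispersion_scale)
    load_g <- ifelse(module > 0, config$loading, 0)
    libsize <- exp(rnorm(n_samp, config$libsize_log_mean,
                         config$libsize_log_sd))

    # transcript multiplicity
    n_tx_per_ogg <- rep(1L, config$n_oggs)
    multi <- runif(config$n_oggs) < config$multi_transcript_frac
    n_tx_per_ogg[multi] <- sample(2:3, sum(multi), replace = TRUE)
    tx_ogg <- rep(seq_len(config$n_oggs), times = n_tx_per_ogg)
    tx_ids <- unlist(lapply(seq_len(config$n_oggs), function(g)
      if (n_tx_per_ogg[g] == 1) ogg_ids[g]
      else paste0(ogg_ids[g], "_t", seq_len(n_tx_per_ogg[g]))))

    # counts
    log_mu <- matrix(log(baseline[tx_ogg]), length(tx_ogg), n_samp)
    in_mod <- module[tx_ogg] > 0
    if (any(in_mod))
      log_mu[in_mod, ] <- log_mu[in_mod, , drop = FALSE] +
        load_g[tx_ogg[in_mod]] * factors[module[tx_ogg[in_mod]], ,
                                         drop = FALSE]
    log_mu <- sweep(log_mu, 2, log(libsize), "+")
    mu <- exp(log_mu)
    counts <- matrix(0L, nrow(mu), n_samp,
                     dimnames = list(tx_ids, samples$sample))
    phi_tx <- phi[tx_ogg]
    for (j in seq_len(n_samp)) {
      pois <- phi_tx < 1e-12
      y <- integer(nrow(mu))
      if (any(pois)) y[pois] <- rpois(sum(pois), mu[pois, j])
      if (any(!pois)) y[!pois] <- rnbinom(sum(!pois), mu = mu[!pois, j],
                                          size = 1 / phi_tx[!pois])
      counts[, j] <- y
    }

    # orthology dropout: whole species column missing for that OGG
    if (config$dropout_prob > 0) {
      drop_mat <- matrix(runif(config$n_oggs * n_sp) < config$dropout_prob,
                         config$n_oggs, n_sp)
      for (sp in seq_len(n_sp)) {
        gone <- which(drop_mat[, sp])
        if (length(gone))
          counts[tx_ogg %in% gone, samples$species == tree$tip.label[sp]] <- NA
      }
    }

    truth <- list(ogg = ogg_ids,
                  module = module,
                  caste_effect = beta_caste,
                  trait_effects = beta_trait,
                  loading = load_g,
                  dispersion = phi,
                  baseline = baseline,
                  caste_associated = as.integer(module > 0),
                  factors = factors,
                  species_effects = u_species,
                  libsize = libsize)
    list(counts = counts,
         samples = samples[, c("sample", "species", "caste", "replicate")],
         ogg_map = data.frame(transcript = tx_ids, ogg = ogg_ids[tx_ogg]),
         truth = truth)
  })
}

#' Simulate per-OGG dN/dS driven by connectivity, expression and caste
#'
#' log(omega) = g0 + g_expr * log(expr) + g_conn * log(conn) + g_caste *
#' caste + g_conn_caste * log(conn) * caste + g_expr_caste * log(expr) *
#' caste + Gaussian noise, where `caste` is the 0/1 indicator of membership
#' in a planted (caste-associated) module.
#'
#' @param truth truth element of [simulate_expression()] output (or any list
#'   with `ogg` and `caste_associated`).
#' @param connectivity,expression positive per-OGG vectors aligned with
#'   `truth$ogg`.
#' @param coeffs numeric length-6 generating coefficients (see
#'   [sim_config()]).
#' @param log_sd sd of log-scale noise.
#' @param seed RNG seed.
#' @return data.frame with columns ogg, omega, expression, connectivity,
#'   caste_associated.
#' @export
simulate_omega <- function(truth, connectivity, expression,
                           coeffs = sim_config()$omega_coeffs,
                           log_sd = 0.5, seed = 1L) {
  if (any(!is.finite(connectivity)) || any(connectivity <= 0))
    stop("connectivity must be positive")
  if (any(!is.finite(expression)) || any(expression <= 0))
    stop("expression must be positive")
  n <- length(truth$ogg)
  stopifnot(length(connectivity) == n, length(expression) == n)
  caste <- as.numeric(truth$caste_associated)
  lc <- log(connectivity); le <- log(expression)
  eta <- coeffs[[1]] + coeffs[[2]] * le + coeffs[[3]] * lc +
    coeffs[[4]] * caste + coeffs[[5]] * lc * caste + coeffs[[6]] * le * caste
  omega <- local_seed(seed, exp(eta + rnorm(n, 0, log_sd)))
  data.frame(ogg = truth$ogg, omega = omega, expression = expression,
             connectivity = connectivity, caste_associated = caste)
}

#' Simulate a random gene-to-term annotation map
#'
#' Each OGG receives `terms_per_gene` distinct terms drawn uniformly from
#' `n_terms` term identifiers.
#'
#' @param n_oggs number of genes; ids `OGG00001`...
#' @param n_terms number of distinct terms.
#' @param terms_per_gene terms assigned to each gene (0 gives an empty map).
#' @param seed RNG seed.
#' @return data.frame with columns ogg, term (long format).
#' @export
simulate_annotations <- function(n_oggs, n_terms, terms_per_gene, seed = 1L) {
  check_scalar(n_oggs, "n_oggs", min = 1, integer = TRUE)
  check_scalar(n_terms, "n_terms", min = 1, integer = TRUE)
  check_scalar(terms_per_gene, "terms_per_gene", min = 0, integer = TRUE)
  if (terms_per_gene > n_terms)
    stop("terms_per_gene cannot exceed n_terms")
  ogg_ids <- sprintf("OGG%05d", seq_len(n_oggs))
  term_ids <- sprintf("TERM%04d", seq_len(n_terms))
  if (terms_per_gene == 0)
    return(data.frame(ogg = character(0), term = character(0)))
  local_seed(seed, {
    picks <- lapply(seq_len(n_oggs), function(g)
      sample(term_ids, terms_per_gene))
    data.frame(ogg = rep(ogg_ids, each = terms_per_gene),
               term = unlist(picks))
  })
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes counts, sample metadata, OGG map, traits, tree, and truth labels
#' in the formats the downstream readers expect (TSV, newick, JSON).
#'
#' @param sim output of [simulate_expression()].
#' @param tree the species tree used.
#' @param traits the species trait table used.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, tree, traits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "samples.tsv", "ogg_map.tsv",
                            "traits.tsv", "tree.nwk", "truth.json"))
  write.table(data.frame(transcript = rownames(sim$counts), sim$counts,
                         check.names = FALSE),
              paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$samples, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$ogg_map, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(traits, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(tree, paths[5])
  jsonlite::write_json(sim$truth, paths[6], auto_unbox = FALSE, digits = NA)
  invisible(paths)
}
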