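#' Pipeline configuration
#'
#' Validated stage-by-stage configuration of the end-to-end synthetic
#' analysis: simulation, matrix building, per-species differential
#' expression, network inference, trait association, overlap resampling,
#' rate regression, and enrichment/preservation. Unknown keys in any stage
#' list are rejected.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param de list: min_count, min_samples (low-count filter), alpha.
#' @param network list: power (NULL = choose by scale-free fit),
#'   candidate_powers, r2_target, mode, min_module_size, merge_cutoff,
#'   min_pairwise_obs, cut_quantile, cut_height_max, max_missing_fraction,
#'   outlier_z.
#' @param mcmc list: n_iter, burn_in, thin, prior_shape, prior_scale,
#'   alpha.
#' @param overlap list: n_draws, direction_aware.
#' @param rates list: n_boot, omega_log_sd.
#' @param enrich list: n_terms, terms_per_gene, alpha.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            de = list(),
                            network = list(),
                            mcmc = list(),
                            overlap = list(),
                            rates = list(),
                            enrich = list()) {
  defaults <- list(
    de = list(min_count = 5, min_samples = 2, alpha = 0.05),
    network = list(power = 8, candidate_powers = c(1:10, seq(12, 20, 2)),
                   r2_target = 0.9, mode = "unsigned", min_module_size = 30,
                   merge_cutoff = 0.2, min_pairwise_obs = 10,
                   cut_quantile = 0.99, cut_height_max = 0.99,
                   max_missing_fraction = 0.5, outlier_z = 3),
    mcmc = list(n_iter = 50000, burn_in = 15000, thin = 10,
                prior_shape = 0.01, prior_scale = 0.01, alpha = 0.05),
    overlap = list(n_draws = 100, direction_aware = TRUE),
    rates = list(n_boot = 1000, omega_log_sd = 0.5),
    enrich = list(n_terms = 200, terms_per_gene = 5, alpha = 0.05))
  user <- list(de = de, network = network, mcmc = mcmc, overlap = overlap,
               rates = rates, enrich = enrich)
  merged <- lapply(names(defaults), function(stage) {
    unknown <- setdiff(names(user[[stage]]), names(defaults[[stage]]))
    if (length(unknown))
      stop("unknown ", stage, " config key(s): ",
           paste(unknown, collapse = ", "))
    utils::modifyList(defaults[[stage]], user[[stage]])
  })
  names(merged) <- names(defaults)
  stopifnot(inherits(sim, "sim_config"))
  sim$seed <- as.integer(seed)
  structure(c(list(seed = as.integer(seed), sim = sim), merged),
            class = "pipeline_config")
}

# Per-species DE at the transcript level, collapsed to OGGs by the member
# transcript with the smallest q (mirrors assigning DE transcripts to their
# orthogroup).
de_by_species <- function(counts, samples, ogg_map, min_count, min_samples,
                          alpha) {
  out <- list()
  for (sp in unique(samples$species)) {
    idx <- samples$species == sp
    sub <- counts[, samples$sample[idx], drop = FALSE]
    grp <- samples$caste[idx]
    # drop transcripts missing (orthology dropout) in this species
    present <- rowSums(!is.na(sub)) > 0
    sub <- sub[present, , drop = FALSE]
    sub <- low_count_filter(sub, min_count, min_samples, grp)
    keep_expr <- rowSums(sub, na.rm = TRUE) > 0
    sub <- sub[keep_expr, , drop = FALSE]
    de_tx <- caste_de_test(sub, grp, alpha = alpha)
    de_tx$ogg <- ogg_map$ogg[match(de_tx$gene, ogg_map$transcript)]
    # representative transcript per OGG: smallest q (NAs last)
    ord <- order(de_tx$ogg, is.na(de_tx$q), de_tx$q)
    de_tx <- de_tx[ord, ]
    de_ogg <- de_tx[!duplicated(de_tx$ogg), ]
    de_ogg$gene <- de_ogg$ogg
    out[[sp]] <- de_ogg[, c("gene", "logFC", "p", "q", "direction",
                            "untestable")]
  }
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> normalize/aggregate/filter -> per-species DE ->
#' network -> trait association -> overlap -> evolutionary rates ->
#' enrichment/preservation, writing every declared output as TSV/JSON under
#' `outdir` plus a manifest with seeds and output hashes. Identical config
#' and seed give identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, a list of in-memory stage results; the manifest is
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  tsv <- function(df, name) {
    path <- file.path(outdir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character(0)

  ## stage: simulate
  tree <- simulate_tree(config$sim$n_species, stage_seed(seed, "tree"))
  traits <- simulate_species_traits(tree, config$sim$trait_switch_rate,
                                    stage_seed(seed, "traits"))
  sim <- simulate_expression(config$sim, tree, traits)
  files <- c(files, write_simulation(sim, tree, traits, outdir))

  ## stage: expression matrix
  counts <- sim$counts
  factors <- tmm_factors(counts)
  logcpm <- log2_cpm(counts, factors)
  ogg_expr <- aggregate_to_ogg(logcpm, sim$ogg_map)
  filt <- filter_oggs(ogg_expr, config$network$max_missing_fraction)
  outliers <- detect_outlier_samples(filt$matrix, config$network$outlier_z)
  net_mat <- filt$matrix[, setdiff(colnames(filt$matrix), outliers),
                         drop = FALSE]
  net_samples <- sim$samples[match(colnames(net_mat), sim$samples$sample), ]
  mds <- mds_coordinates(filt$matrix)
  files <- c(files,
             tsv(data.frame(sample = names(factors), factor = factors),
                 "tmm_factors.tsv"),
             tsv(filt$removed, "removed_oggs.tsv"),
             tsv(data.frame(sample = rownames(mds), mds),
                 "mds_coordinates.tsv"))

  ## stage: differential expression
  de_list <- de_by_species(counts, sim$samples, sim$ogg_map,
                           config$de$min_count, config$de$min_samples,
                           config$de$alpha)
  for (sp in names(de_list))
    files <- c(files, tsv(de_list[[sp]], paste0("de_", sp, ".tsv")))

  ## stage: network
  if (is.null(config$network$power)) {
    pst <- pick_soft_threshold(net_mat, config$network$candidate_powers,
                               config$network$r2_target,
                               mode = config$network$mode,
                               min_pairwise_obs =
                                 config$network$min_pairwise_obs)
    power <- pst$power
    files <- c(files, tsv(pst$fit_table, "soft_threshold_fit.tsv"))
  } else power <- config$network$power
  adj <- adjacency(net_mat, power, config$network$mode,
                   config$network$min_pairwise_obs)
  tom <- topological_overlap(adj)
  assignment <- cluster_modules(tom, config$network$min_module_size,
                                config$network$cut_quantile,
                                config$network$cut_height_max)
  assignment <- merge_modules(net_mat, assignment,
                              config$network$merge_cutoff)
  eg <- module_eigengenes(net_mat, assignment)
  conn <- connectivity(adj, assignment)
  files <- c(files,
             tsv(data.frame(ogg = rownames(net_mat),
                            module = as.integer(assignment)),
                 "module_assignment.tsv"),
             tsv(data.frame(module = rownames(eg$eigengenes),
                            eg$eigengenes, check.names = FALSE),
                 "eigengenes.tsv"),
             tsv(conn, "connectivity.tsv"))

  ## stage: trait association
  C <- phylo_covariance(tree)
  design <- data.frame(
    caste = net_samples$caste,
    traits[match(net_samples$species, traits$species),
           c("worker_sterility", "queen_number", "invasiveness")],
    species = net_samples$species)
  fits <- lapply(seq_len(nrow(eg$eigengenes)), function(i)
    fit_phylo_mixed_model(eg$eigengenes[i, ], design, C,
                          n_iter = config$mcmc$n_iter,
                          burn_in = config$mcmc$burn_in,
                          thin = config$mcmc$thin,
                          prior_shape = config$mcmc$prior_shape,
                          prior_scale = config$mcmc$prior_scale,
                          seed = stage_seed(seed, "association") + i))
  names(fits) <- rownames(eg$eigengenes)
  labels <- classify_modules(fits, config$mcmc$alpha)
  assoc <- do.call(rbind, lapply(names(fits), function(m)
    data.frame(module = m, fits[[m]]$summary)))
  files <- c(files, tsv(assoc, "association.tsv"),
             tsv(labels, "module_labels.tsv"))

  ## stage: overlap
  curve <- deg_overlap_curve(de_list,
                             n_draws = config$overlap$n_draws,
                             direction_aware =
                               config$overlap$direction_aware,
                             seed = stage_seed(seed, "overlap"))
  consistent <- consistent_deg_set(de_list,
                                   config$overlap$direction_aware)
  files <- c(files,
             tsv(curve[, c("k", "mean", "sd")], "overlap_curve.tsv"),
             tsv(consistent, "consistent_degs.tsv"))

  ## stage: evolutionary rates
  ogg_conn <- setNames(conn$kTotal, conn$gene)
  mean_expr <- rowMeans(2^net_mat - 1, na.rm = TRUE)
  in_net <- sim$truth$ogg %in% names(ogg_conn)
  truth_net <- lapply(sim$truth[c("ogg", "caste_associated")],
                      function(x) x[in_net])
  evo_conn <- pmax(ogg_conn[truth_net$ogg], 1e-6)
  evo_expr <- pmax(mean_expr[truth_net$ogg], 1e-6)
  omega_tab <- simulate_omega(truth_net, evo_conn, evo_expr,
                              coeffs = config$sim$omega_coeffs,
                              log_sd = config$rates$omega_log_sd,
                              seed = stage_seed(seed, "omega"))
  module_caste <- setNames(labels$caste, labels$module)
  gene_module <- paste0("ME", assignment[omega_tab$ogg])
  omega_tab$caste_label <- ifelse(assignment[omega_tab$ogg] == 0, "NTA",
                                  module_caste[gene_module])
  omega_tab$caste_label[omega_tab$caste_label == "NTA"] <- "NTA"
  rate_fits <- fit_rate_models(omega_tab, n_boot = config$rates$n_boot,
                               seed = stage_seed(seed, "rates"))
  rate_tab <- do.call(rbind, lapply(names(rate_fits), function(m)
    if (!is.null(rate_fits[[m]]))
      data.frame(model = m, rate_fits[[m]]$coefficients)))
  files <- c(files, tsv(omega_tab, "omega.tsv"),
             tsv(rate_tab, "rate_models.tsv"))

  ## stage: enrichment & preservation
  annot <- simulate_annotations(config$sim$n_oggs, config$enrich$n_terms,
                                config$enrich$terms_per_gene,
                                stage_seed(seed, "annotations"))
  enrich <- do.call(rbind, lapply(
    sort(unique(assignment[assignment > 0])), function(m)
      data.frame(module = paste0("ME", m),
                 hypergeometric_enrichment(
                   names(assignment)[assignment == m], annot))))
  truth_labels <- setNames(sim$truth$module, sim$truth$ogg)
  pres <- module_preservation(assignment,
                              truth_labels[names(assignment)],
                              alpha = config$enrich$alpha)
  files <- c(files, tsv(enrich, "enrichment.tsv"),
             tsv(pres$significant_pairs, "preservation_pairs.tsv"))
  files <- c(files, tsv(annot, "annotations.tsv"))

  ## manifest
  files <- unique(normalizePath(files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("castenet")),
    seed = seed,
    n_modules = length(unique(assignment[assignment > 0])),
    outlier_samples = as.character(outliers),
    files = lapply(setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(outdir, f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(tree = tree, traits = traits, sim = sim,
                 factors = factors, ogg_expr = ogg_expr, filtered = filt,
                 outliers = outliers, de = de_list, power = power,
                 assignment = assignment, eigengenes = eg,
                 connectivity = conn, fits = fits, labels = labels,
                 overlap_curve = curve, consistent_degs = consistent,
                 omega = omega_tab, rate_fits = rate_fits,
                 enrichment = enrich, preservation = pres,
                 manifest = manifest))
}
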