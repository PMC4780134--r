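# Cross-species consistency of differential expression and enrichment.

# Extract the significant gene set (optionally direction-tagged) from one
# species' DE table.
de_sig_set <- function(de, direction_aware = TRUE) {
  sig <- de[!is.na(de$q) & de$direction != "ns", , drop = FALSE]
  if (direction_aware) paste(sig$gene, sig$direction, sep = "|")
  else unique(sig$gene)
}

#' Genes consistently caste-biased across all species
#'
#' Intersection of the significant DE gene sets across species; with
#' `direction_aware` a gene must be biased toward the same caste in every
#' species.
#'
#' @param de_by_species named list of DE tables from [caste_de_test()].
#' @param direction_aware require a consistent direction (default TRUE).
#' @return data.frame with columns gene and (if direction-aware) direction.
#' @export
consistent_deg_set <- function(de_by_species, direction_aware = TRUE) {
  sets <- lapply(de_by_species, de_sig_set, direction_aware = direction_aware)
  common <- Reduce(intersect, sets)
  if (direction_aware) {
    parts <- strsplit(common, "|", fixed = TRUE)
    data.frame(gene = vapply(parts, `[`, "", 1),
               direction = vapply(parts, `[`, "", 2))
  } else data.frame(gene = common)
}

# Shared machinery of the two overlap curves: repeatedly sample k species
# without replacement and count elements present in all k sets.
overlap_curve <- function(sets, k_values, n_draws, seed) {
  n_sp <- length(sets)
  k_values <- k_values[k_values >= 2 & k_values <= n_sp]
  local_seed(seed, {
    rows <- lapply(k_values, function(k) {
      counts <- vapply(seq_len(n_draws), function(d) {
        pick <- sample.int(n_sp, k)
        length(Reduce(intersect, sets[pick]))
      }, numeric(1))
      data.frame(k = k, mean = mean(counts), sd = sd(counts),
                 draws = I(list(counts)))
    })
    do.call(rbind, rows)
  })
}

#' Bootstrap overlap curve of caste DE genes across species
#'
#' For each k, repeatedly samples k species without replacement and counts
#' the genes significantly caste-biased (q < alpha) in all k of them, with
#' the same direction when `direction_aware`.
#'
#' @param de_by_species named list of per-species DE tables.
#' @param k_values numbers of species to sample (default 2..n_species).
#' @param n_draws resampling draws per k (default 100).
#' @param direction_aware require consistent direction (default TRUE).
#' @param seed RNG seed.
#' @return data.frame: k, mean, sd, draws (list column of per-draw counts).
#' @export
deg_overlap_curve <- function(de_by_species,
                              k_values = seq(2, length(de_by_species)),
                              n_draws = 100, direction_aware = TRUE,
                              seed = 1L) {
  sets <- lapply(de_by_species, de_sig_set, direction_aware = direction_aware)
  overlap_curve(sets, k_values, n_draws, seed)
}

#' Bootstrap overlap curve of enriched terms across species
#'
#' As [deg_overlap_curve()] but over sets of enriched term identifiers.
#'
#' @param terms_by_species named list of character vectors of enriched
#'   terms, one per species.
#' @param k_values,n_draws,seed as in [deg_overlap_curve()].
#' @return data.frame: k, mean, sd, draws.
#' @export
term_overlap_curve <- function(terms_by_species,
                               k_values = seq(2, length(terms_by_species)),
                               n_draws = 100, seed = 1L) {
  overlap_curve(lapply(terms_by_species, unique), k_values, n_draws, seed)
}

#' Compare consistent DE counts between two species subsets
#'
#' Computes [consistent_deg_set()] within each of two named species subsets
#' (e.g. one genus vs an equally sized random draw of other species) and
#' returns both counts.
#'
#' @param de_by_species named list of per-species DE tables.
#' @param group_a_species,group_b_species character vectors of species
#'   names.
#' @param direction_aware require consistent direction (default TRUE).
#' @return list with `count_a`, `count_b`, `set_a`, `set_b`.
#' @export
subset_overlap_compare <- function(de_by_species, group_a_species,
                                   group_b_species,
                                   direction_aware = TRUE) {
  missing <- setdiff(c(group_a_species, group_b_species),
                     names(de_by_species))
  if (length(missing))
    stop("species not in DE list: ", paste(missing, collapse = ", "))
  set_a <- consistent_deg_set(de_by_species[group_a_species],
                              direction_aware)
  set_b <- consistent_deg_set(de_by_species[group_b_species],
                              direction_aware)
  list(count_a = nrow(set_a), count_b = nrow(set_b),
       set_a = set_a, set_b = set_b)
}
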