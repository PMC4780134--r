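# Term enrichment per module and cross-study module preservation.

#' Hypergeometric term enrichment of a gene set
#'
#' Upper-tail hypergeometric test per term: the probability of observing at
#' least the overlap between the module and the term's genes, given the
#' module size, term size, and annotated universe; BH adjustment across
#' terms.
#'
#' @param module_genes character vector of genes in the module.
#' @param annotation_map data.frame with columns ogg, term; the annotated
#'   genes define the universe.
#' @return data.frame per term: term, overlap, module_size, term_size,
#'   universe_size, p, q (sorted by p).
#' @export
hypergeometric_enrichment <- function(module_genes, annotation_map) {
  universe <- unique(annotation_map$ogg)
  module_genes <- intersect(unique(module_genes), universe)
  n_univ <- length(universe)
  n_mod <- length(module_genes)
  by_term <- split(annotation_map$ogg, annotation_map$term)
  rows <- lapply(names(by_term), function(tm) {
    term_genes <- unique(by_term[[tm]])
    k <- length(intersect(term_genes, module_genes))
    m <- length(term_genes)
    p <- phyper(k - 1, m, n_univ - m, n_mod, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, module_size = n_mod, term_size = m,
               universe_size = n_univ, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p), ]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by the minimum-likelihood method: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (a small
#' relative tolerance guards against floating-point ties).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param alternative "two.sided" (default), "greater" or "less" on the
#'   [1,1] cell.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  if (m == 0 || n == 0 || k == 0 || sum(table[, 2]) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
              greater = sum(probs[support >= a]),
              less = sum(probs[support <= a]))
  min(1, p)
}

#' Cross-study module preservation by membership cross-tabulation
#'
#' For every pair of modules (one from each labeling), tests whether genes
#' assigned to the first are over-represented in the second with a
#' one-per-pair 2x2 Fisher's exact test, BH-adjusted jointly across all
#' pairs; significant pairs at q < alpha are listed.
#'
#' @param labels_a,labels_b named vectors of module labels (names are gene
#'   ids in each study's namespace; 0 = unassigned genes are kept as
#'   background).
#' @param gene_map data.frame with columns gene_a, gene_b linking
#'   identifiers between the studies; if NULL, names are matched directly.
#' @param alpha FDR threshold (default 0.05).
#' @return list: `counts` (module_a x module_b gene-count matrix), `p` and
#'   `q` matrices, `significant_pairs` (data.frame module_a, module_b,
#'   overlap, p, q), `n_unmapped` genes dropped.
#' @export
module_preservation <- function(labels_a, labels_b, gene_map = NULL,
                                alpha = 0.05) {
  if (is.null(gene_map)) {
    shared <- intersect(names(labels_a), names(labels_b))
    gene_map <- data.frame(gene_a = shared, gene_b = shared)
    n_unmapped <- length(union(names(labels_a), names(labels_b))) -
      length(shared)
  } else {
    ok <- gene_map$gene_a %in% names(labels_a) &
      gene_map$gene_b %in% names(labels_b)
    n_unmapped <- sum(!ok)
    gene_map <- gene_map[ok, , drop = FALSE]
  }
  la <- labels_a[gene_map$gene_a]
  lb <- labels_b[gene_map$gene_b]
  n <- length(la)
  mods_a <- sort(unique(la[la != 0]))
  mods_b <- sort(unique(lb[lb != 0]))
  counts <- matrix(0L, length(mods_a), length(mods_b),
                   dimnames = list(paste0("A", mods_a), paste0("B", mods_b)))
  pmat <- counts * NA_real_
  for (i in seq_along(mods_a)) {
    ina <- la == mods_a[i]
    for (j in seq_along(mods_b)) {
      inb <- lb == mods_b[j]
      tab <- matrix(c(sum(ina & inb), sum(ina & !inb),
                      sum(!ina & inb), sum(!ina & !inb)), 2)
      counts[i, j] <- tab[1, 1]
      pmat[i, j] <- fisher_exact_2x2(tab, alternative = "greater")
    }
  }
  qmat <- matrix(bh_fdr(as.vector(pmat)), nrow(pmat),
                 dimnames = dimnames(pmat))
  sig <- which(qmat < alpha, arr.ind = TRUE)
  significant_pairs <- data.frame(
    module_a = rownames(qmat)[sig[, 1]],
    module_b = colnames(qmat)[sig[, 2]],
    overlap = counts[sig], p = pmat[sig], q = qmat[sig])
  significant_pairs <- significant_pairs[order(significant_pairs$p), ]
  list(counts = counts, p = pmat, q = qmat,
       significant_pairs = significant_pairs, n_unmapped = n_unmapped)
}
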