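#' Weighted co-expression adjacency matrix
#'
#' Soft-thresholded adjacency from Pearson correlations over samples:
#' `|cor|^power` (unsigned, default) or `((1 + cor) / 2)^power` (signed).
#' Correlations use pairwise-complete observations; pairs with fewer than
#' `min_pairwise_obs` shared non-missing samples get adjacency 0.
#'
#' @param mat expression matrix, genes x samples (NA = missing).
#' @param power soft-thresholding exponent beta (default 8).
#' @param mode "unsigned" or "signed".
#' @param min_pairwise_obs minimum shared observations per pair
#'   (default 10).
#' @return symmetric adjacency matrix in [0, 1] with unit diagonal.
#' @export
adjacency <- function(mat, power = 8, mode = c("unsigned", "signed"),
                      min_pairwise_obs = 10) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  r <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  obs <- crossprod(!is.na(t(mat)))
  r[obs < min_pairwise_obs] <- 0
  a <- if (mode == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with the
#' sum over u != i, j, connectivities k excluding the diagonal, and unit
#' diagonal.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @return symmetric TOM matrix in [0, 1], diagonal 1.
#' @export
topological_overlap <- function(adj) {
  a0 <- adj
  diag(a0) <- 0
  k <- rowSums(a0)
  numer <- a0 %*% a0 + a0
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- numer / denom
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' For each candidate power, gene connectivities are computed, binned on
#' log10(k), and log10 of the frequency is regressed on log10 of the mean
#' binned connectivity. The signed fit index is -sign(slope) * R^2, so a
#' decaying degree distribution scores positively. Returns the smallest
#' power reaching `r2_target`, or the best-fitting power with a warning.
#'
#' @param mat expression matrix, genes x samples.
#' @param candidate_powers integer powers to scan.
#' @param r2_target signed R^2 target (default 0.9).
#' @param n_bins connectivity histogram bins (default 10).
#' @param mode,min_pairwise_obs passed to [adjacency()].
#' @return list with elements `power` and `fit_table` (power, r2_signed,
#'   slope, mean_k).
#' @export
pick_soft_threshold <- function(mat, candidate_powers = c(1:10, seq(12, 20, 2)),
                                r2_target = 0.9, n_bins = 10,
                                mode = "unsigned", min_pairwise_obs = 10) {
  mat <- as.matrix(mat)
  base <- adjacency(mat, power = 1, mode = mode,
                    min_pairwise_obs = min_pairwise_obs)
  diag(base) <- 0
  fit <- do.call(rbind, lapply(candidate_powers, function(beta) {
    k <- rowSums(base^beta)
    k <- k[k > 0]
    cuts <- cut(k, breaks = n_bins)
    freq <- tapply(k, cuts, length)
    km <- tapply(k, cuts, mean)
    ok <- !is.na(freq) & freq > 0
    if (sum(ok) < 3)
      return(data.frame(power = beta, r2_signed = NA, slope = NA,
                        mean_k = mean(k)))
    f <- lm(log10(freq[ok]) ~ log10(km[ok]))
    r2 <- summary(f)$r.squared
    slope <- coef(f)[2]
    data.frame(power = beta, r2_signed = -sign(slope) * r2, slope = slope,
               mean_k = mean(k))
  }))
  rownames(fit) <- NULL
  hit <- which(!is.na(fit$r2_signed) & fit$r2_signed >= r2_target)
  if (length(hit)) {
    power <- fit$power[hit[1]]
  } else {
    power <- fit$power[which.max(fit$r2_signed)]
    warning("no candidate power reached the scale-free fit target; ",
            "returning the best-fitting power (", power, ")")
  }
  list(power = power, fit_table = fit)
}

#' Detect co-expression modules by hierarchical clustering of the TOM
#'
#' Average-linkage clustering on 1 - TOM, cut at the `cut_quantile`
#' quantile of the merge heights, capped at the absolute dissimilarity
#' `cut_height_max` (so that structureless data, where all merges happen
#' near dissimilarity 1, yields no modules). Clusters smaller than
#' `min_module_size` are set to label 0 (unassigned); retained modules are
#' relabeled 1..k by decreasing size.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size minimum module size (default 30).
#' @param cut_quantile quantile of merge heights at which to cut
#'   (default 0.99).
#' @param cut_height_max absolute ceiling on the cut height (default 0.99).
#' @return named integer vector of module labels (0 = unassigned) with the
#'   dendrogram attached as attribute `"dendrogram"`.
#' @export
cluster_modules <- function(tom, min_module_size = 30, cut_quantile = 0.99,
                            cut_height_max = 0.99) {
  d <- 1 - tom
  h <- hclust(as.dist(d), method = "average")
  cut_h <- min(quantile(h$height, cut_quantile), cut_height_max)
  raw <- cutree(h, h = cut_h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  }
  names(labels) <- rownames(tom)
  attr(labels, "dendrogram") <- h
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of the
#' module's standardized (per-gene mean 0, sd 1; missing entries imputed by
#' the gene mean) gene x sample matrix: the first principal component of
#' the module expression, one value per sample, unit Euclidean norm, sign
#' oriented so the mean correlation with member genes is positive.
#'
#' @param mat expression matrix, genes x samples.
#' @param assignment integer module labels from [cluster_modules()].
#' @return list with `eigengenes` (module x sample matrix, rows `ME1`...)
#'   and `var_explained` (fraction of module variance captured).
#' @export
module_eigengenes <- function(mat, assignment) {
  mat <- as.matrix(mat)
  mods <- sort(unique(assignment[assignment > 0]))
  if (!length(mods)) stop("no modules in assignment")
  eg <- matrix(NA_real_, length(mods), ncol(mat),
               dimnames = list(paste0("ME", mods), colnames(mat)))
  ve <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    x <- mat[assignment == mods[i], , drop = FALSE]
    xs <- t(apply(x, 1, function(r) {
      r[is.na(r)] <- mean(r, na.rm = TRUE)
      s <- sd(r)
      if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
    sv <- svd(xs)
    v <- sv$v[, 1]
    cors <- suppressWarnings(cor(v, t(xs)))
    if (mean(cors, na.rm = TRUE) < 0) v <- -v
    eg[i, ] <- v
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, var_explained = ve)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the most similar eigengenes
#' whenever their dissimilarity (1 - correlation) is below `merge_cutoff`,
#' recomputing eigengenes after each merge, to a fixed point. The final
#' labeling is independent of pair processing order.
#'
#' @param mat expression matrix, genes x samples.
#' @param assignment integer module labels.
#' @param merge_cutoff eigengene dissimilarity threshold (default 0.2).
#' @return relabeled integer assignment (1..k by decreasing size,
#'   0 unchanged).
#' @export
merge_modules <- function(mat, assignment, merge_cutoff = 0.2) {
  assignment <- as.integer(assignment)
  names(assignment) <- rownames(mat)
  repeat {
    mods <- sort(unique(assignment[assignment > 0]))
    if (length(mods) < 2) break
    eg <- module_eigengenes(mat, assignment)$eigengenes
    cc <- cor(t(eg))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - max(cc) >= merge_cutoff) break
    a <- mods[best[1]]; b <- mods[best[2]]
    assignment[assignment == max(a, b)] <- min(a, b)
  }
  # relabel by decreasing size
  mods <- sort(unique(assignment[assignment > 0]))
  if (length(mods)) {
    sizes <- table(factor(assignment[assignment > 0], levels = mods))
    new <- integer(length(assignment))
    ord <- mods[order(-sizes)]
    for (i in seq_along(ord)) new[assignment == ord[i]] <- i
    names(new) <- names(assignment)
    assignment <- new
  }
  assignment
}

#' Whole-network and intramodular connectivity
#'
#' kTotal is the row sum of the adjacency excluding the diagonal; kWithin
#' restricts the sum to genes of the same module (0 for unassigned genes).
#'
#' @param adj adjacency matrix.
#' @param assignment integer module labels.
#' @return data.frame: gene, module, kTotal, kWithin.
#' @export
connectivity <- function(adj, assignment) {
  a0 <- adj
  diag(a0) <- 0
  k_total <- rowSums(a0)
  k_within <- numeric(nrow(a0))
  for (m in unique(assignment[assignment > 0])) {
    idx <- assignment == m
    k_within[idx] <- rowSums(a0[idx, idx, drop = FALSE])
  }
  data.frame(gene = rownames(adj), module = as.integer(assignment),
             kTotal = k_total, kWithin = k_within, row.names = NULL)
}
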