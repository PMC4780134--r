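#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-library normalization factors from a doubly trimmed,
#' precision-weighted mean of log2 expression ratios against a reference
#' library. For each sample, M (log2 count ratio vs the reference) and A
#' (average log2 abundance) are computed over genes with positive,
#' non-missing counts in both libraries; the most extreme `trim_m` fraction
#' of M values and `trim_a` fraction of A values are trimmed on each side,
#' and the factor is 2 to the inverse-asymptotic-variance weighted mean of
#' the remaining M values. Factors are renormalized to geometric mean 1.
#'
#' The returned factor is a relative *effective depth*: it absorbs both
#' sequencing depth and compositional differences, so normalized expression
#' is `counts / factor` (up to a constant) and model offsets are
#' `log(factor)`.
#'
#' @param counts non-negative count matrix, genes x samples (NA = missing).
#' @param trim_m,trim_a two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05).
#' @param reference reference sample name or index; by default the library
#'   whose upper-quartile expression (relative to depth) is closest to the
#'   mean upper quartile.
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        reference = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM requires at least 2 samples")
  lib <- colSums(counts, na.rm = TRUE)
  if (any(lib <= 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  if (is.null(reference)) {
    uq <- vapply(seq_len(ncol(counts)), function(j)
      quantile(counts[, j], 0.75, na.rm = TRUE) / lib[j], numeric(1))
    reference <- which.min(abs(uq - mean(uq)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(counts))
    if (is.na(reference)) stop("reference sample not found")
  }
  yr <- counts[, reference]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == reference) return(1)
    ys <- counts[, j]
    ok <- !is.na(ys) & !is.na(yr) & ys > 0 & yr > 0
    if (!any(ok)) stop("no usable genes between sample ", j,
                       " and the reference")
    M <- log2(ys[ok]) - log2(yr[ok])
    A <- (log2(ys[ok]) + log2(yr[ok])) / 2
    w <- (lib[j] - ys[ok]) / (lib[j] * ys[ok]) +
      (lib[reference] - yr[ok]) / (lib[reference] * yr[ok])
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "average")
    rA <- rank(A, ties.method = "average")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)
    wt <- 1 / w[keep]
    wt[!is.finite(wt)] <- max(wt[is.finite(wt)], 1)
    2^(sum(M[keep] * wt) / sum(wt))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Remove genes with too few counts for testing
#'
#' Keeps genes with `count >= min_count` in at least `min_samples` samples
#' of at least one group (typically a caste); with `min_count = 0` the
#' matrix is returned unchanged.
#'
#' @param counts count matrix, genes x samples.
#' @param min_count minimum count.
#' @param min_samples minimum number of samples reaching `min_count`.
#' @param groups optional factor of length ncol(counts); if NULL all samples
#'   form one group.
#' @return the filtered count matrix.
#' @export
low_count_filter <- function(counts, min_count, min_samples, groups = NULL) {
  counts <- as.matrix(counts)
  if (min_count <= 0) return(counts)
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  groups <- as.factor(groups)
  pass <- !is.na(counts) & counts >= min_count
  keep <- rep(FALSE, nrow(counts))
  for (g in levels(groups))
    keep <- keep | rowSums(pass[, groups == g, drop = FALSE]) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Aggregate transcript expression to orthologous gene groups
#'
#' Per OGG and sample, the arithmetic mean of the member transcripts'
#' values. Transcripts absent from the map are dropped; an OGG missing
#' (NA) in a species stays missing for all of that species' samples.
#'
#' @param mat numeric matrix, transcripts x samples (counts or normalized
#'   expression).
#' @param ogg_map data.frame with columns transcript, ogg.
#' @return numeric matrix, OGGs x samples.
#' @export
aggregate_to_ogg <- function(mat, ogg_map) {
  mat <- as.matrix(mat)
  unknown <- setdiff(ogg_map$transcript, rownames(mat))
  if (length(unknown))
    stop("ogg_map references unknown transcripts: ",
         paste(head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) " ...")
  sub <- mat[ogg_map$transcript, , drop = FALSE]
  sums <- rowsum(sub, group = ogg_map$ogg)
  n <- as.vector(table(ogg_map$ogg)[rownames(sums)])
  sums / n
}

#' Filter OGGs on missingness and variance
#'
#' Removes OGGs whose fraction of missing samples exceeds
#' `max_missing_fraction`, and (optionally) OGGs with zero variance across
#' their non-missing entries; every removal is reported with its reason.
#'
#' @param mat OGG x sample expression matrix (NA = missing).
#' @param max_missing_fraction maximum tolerated missing fraction
#'   (default 0.5).
#' @param require_variance drop zero-variance rows (default TRUE).
#' @return list with elements `matrix` (retained rows) and `removed`
#'   (data.frame ogg, reason).
#' @export
filter_oggs <- function(mat, max_missing_fraction = 0.5,
                        require_variance = TRUE) {
  mat <- as.matrix(mat)
  miss_frac <- rowMeans(is.na(mat))
  too_missing <- miss_frac > max_missing_fraction
  zero_var <- rep(FALSE, nrow(mat))
  if (require_variance) {
    v <- apply(mat, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) 0 else var(x)
    })
    zero_var <- !too_missing & v == 0
  }
  reason <- ifelse(too_missing, "too many missing samples",
                   ifelse(zero_var, "zero variance", NA_character_))
  removed <- data.frame(ogg = rownames(mat)[!is.na(reason)],
                        reason = reason[!is.na(reason)])
  list(matrix = mat[!(too_missing | zero_var), , drop = FALSE],
       removed = removed)
}

#' Flag outlier samples by average distance
#'
#' Samples are clustered by average linkage on the Euclidean distance of
#' standardized expression; a sample is flagged when its mean distance to
#' all other samples exceeds the mean of those means plus `z_threshold`
#' standard deviations.
#'
#' @param mat OGG x sample expression matrix.
#' @param z_threshold flagging threshold in SD units (default 3).
#' @return character vector of outlier sample names, with the average-
#'   linkage dendrogram attached as attribute `"dendrogram"`.
#' @export
detect_outlier_samples <- function(mat, z_threshold = 3) {
  mat <- as.matrix(mat)
  if (nrow(mat) == 0 || ncol(mat) == 0) stop("empty expression matrix")
  z <- t(apply(mat, 1, function(x) {
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) s <- 1
    (x - mean(x, na.rm = TRUE)) / s
  }))
  d <- dist(t(z))
  dm <- as.matrix(d)
  mean_d <- rowSums(dm, na.rm = TRUE) / (ncol(dm) - 1)
  flag <- mean_d > mean(mean_d) + z_threshold * sd(mean_d)
  out <- colnames(mat)[flag]
  attr(out, "dendrogram") <- hclust(d, method = "average")
  out
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson MDS on the dissimilarity 1 - Pearson correlation between
#' samples (pairwise-complete observations); coordinates are centered.
#'
#' @param mat OGG x sample expression matrix.
#' @param n_dims number of output dimensions (default 2).
#' @return samples x n_dims coordinate matrix.
#' @export
mds_coordinates <- function(mat, n_dims = 2) {
  mat <- as.matrix(mat)
  d <- 1 - cor(mat, use = "pairwise.complete.obs")
  d[d < 0] <- 0
  coords <- cmdscale(as.dist(d), k = n_dims)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}

#' Normalized log2 counts-per-million
#'
#' log2(cpm + 1) using TMM effective-depth factors; the scale used for the
#' network and MDS stages (raw normalized counts are kept for differential
#' expression).
#'
#' @param counts count matrix, genes x samples.
#' @param factors TMM factors from [tmm_factors()] (effective relative
#'   depth, geometric mean 1); computed if NULL.
#' @return matrix of log2(cpm + 1) values.
#' @export
log2_cpm <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  depth <- factors * exp(mean(log(colSums(counts, na.rm = TRUE))))
  log2(sweep(counts, 2, depth, "/") * 1e6 + 1)
}
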