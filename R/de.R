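# Negative-binomial differential expression with an explicit,
# fixed-dispersion likelihood-ratio test. Mean parameterization:
# Var = mu + phi * mu^2 (phi = 0 recovers the Poisson).

# NB log-likelihood at fixed dispersion, elementwise; y and mu conformable.
nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  if (phi < 1e-12) {
    ifelse(y > 0, y * log(mu), 0) - mu - lgamma(y + 1)
  } else {
    r <- 1 / phi
    lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
      ifelse(y > 0, y * log(phi * mu / (1 + phi * mu)), 0) -
      r * log1p(phi * mu)
  }
}

# Vectorized NB intercept fit with offsets: for each gene (row) maximize the
# NB likelihood of mu_ij = exp(b_i + o_j) over b_i, with per-gene fixed
# dispersion and an observation mask (for missing entries). Fisher scoring.
nb_fit_intercept <- function(y, offset, phi, mask = NULL, max_iter = 100L) {
  y <- as.matrix(y)
  if (is.null(mask)) mask <- !is.na(y)
  y0 <- ifelse(mask, y, 0)
  s <- matrix(exp(offset), nrow(y), ncol(y), byrow = TRUE) * mask
  tot <- rowSums(y0)
  b <- log(pmax(tot, 0.5) / pmax(rowSums(s), 1e-12)) -
    ifelse(tot > 0, 0, 30)
  for (it in seq_len(max_iter)) {
    mu <- exp(b) * s
    denom <- 1 + phi * mu
    score <- rowSums((y0 - mu) / denom)
    info <- rowSums(mu / denom)
    step <- ifelse(info > 0, score / info, 0)
    step <- pmax(pmin(step, 5), -5)
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  mu <- exp(b) * s
  ll <- rowSums(nb_loglik_mat(y0, mu, phi) * mask)
  list(b = b, loglik = ll)
}

# nb_loglik over a matrix with per-row phi.
nb_loglik_mat <- function(y, mu, phi) {
  out <- matrix(0, nrow(y), ncol(y))
  pois <- phi < 1e-12
  if (any(pois))
    out[pois, ] <- nb_loglik(y[pois, , drop = FALSE],
                             mu[pois, , drop = FALSE], 0)
  for (i in which(!pois))
    out[i, ] <- nb_loglik(y[i, ], mu[i, ], phi[i])
  out
}

#' Estimate per-gene NB dispersions
#'
#' Method-of-moments dispersion per gene, computed within groups and pooled,
#' then shrunk toward a trended dispersion (lowess of the raw estimates on
#' average log expression) with weight n / (n + n0).
#'
#' @param counts count matrix, genes x samples (NA = missing).
#' @param groups factor of group labels (>= 2 samples per group).
#' @param n0 prior weight of the trend (default 100: with few replicates the
#'   per-gene moment estimate is noisy, and a trend-dominant shrinkage gives
#'   calibrated type-I error).
#' @return data.frame with columns gene, mean, dispersion_raw, dispersion,
#'   untestable.
#' @export
estimate_dispersions <- function(counts, groups, n0 = 100) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  n <- ncol(counts)
  phi_raw <- rep(0, nrow(counts))
  wsum <- rep(0, nrow(counts))
  for (g in levels(groups)) {
    sub <- counts[, groups == g, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    v <- apply(sub, 1, var, na.rm = TRUE)
    nj <- rowSums(!is.na(sub))
    ok <- !is.na(m) & m > 0 & nj >= 2 & !is.na(v)
    # denominator m^2 - v/n corrects the plug-in bias of the group mean
    denom <- pmax(m^2 - v / pmax(nj, 1), m^2 / 2)
    contrib <- ifelse(ok, pmax((v - m) / denom, 0), 0)
    w <- ifelse(ok, nj - 1, 0)
    phi_raw <- phi_raw + contrib * w
    wsum <- wsum + w
  }
  phi_raw <- ifelse(wsum > 0, phi_raw / wsum, 0)
  mean_expr <- rowMeans(counts, na.rm = TRUE)
  mean_expr[is.na(mean_expr)] <- 0
  untestable <- mean_expr == 0 | wsum == 0
  # trended dispersion on log mean expression
  ok <- !untestable & mean_expr > 0
  trend <- rep(0, nrow(counts))
  if (sum(ok) >= 10) {
    lo <- lowess(log(mean_expr[ok]), phi_raw[ok], f = 0.5)
    tr <- approx(lo$x, lo$y, xout = log(mean_expr[ok]), rule = 2,
                 ties = mean)$y
    trend[ok] <- pmax(tr, 0)
  } else trend[ok] <- mean(phi_raw[ok])
  phi <- (n * phi_raw + n0 * trend) / (n + n0)
  phi[untestable] <- 0
  data.frame(gene = rownames(counts), mean = mean_expr,
             dispersion_raw = phi_raw, dispersion = phi,
             untestable = untestable, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values (wraps [stats::p.adjust()]); NAs are preserved.
#'
#' @param pvalues numeric vector of p-values.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) p.adjust(pvalues, method = "BH")

#' Queen-vs-worker NB differential expression test
#'
#' Per gene, a likelihood-ratio test of a two-group NB GLM (caste means)
#' against the intercept-only model, with log effective-depth offsets and
#' dispersion held fixed at the shrunken estimate; df = 1. P-values are
#' BH-adjusted; a gene is significant at q < alpha, with direction given by
#' the sign of the queen-vs-worker fold change.
#'
#' @param counts count matrix, genes x samples (one species).
#' @param groups factor/character with levels containing "queen" and
#'   "worker".
#' @param factors TMM effective-depth factors (computed if NULL).
#' @param alpha significance level on q (default 0.05).
#' @param dispersions optional data.frame from [estimate_dispersions()].
#' @return data.frame: gene, logFC (log2 queen/worker), p, q, direction
#'   ("queen", "worker" or "ns"), untestable.
#' @export
caste_de_test <- function(counts, groups, factors = NULL, alpha = 0.05,
                          dispersions = NULL) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (!all(groups %in% c("queen", "worker")))
    stop("groups must be 'queen' or 'worker'")
  res <- data.frame(gene = rownames(counts), logFC = NA_real_, p = NA_real_,
                    q = NA_real_, direction = "ns", untestable = TRUE,
                    row.names = NULL)
  if (min(table(groups)) < 2) {
    warning("a caste has fewer than 2 replicates; all genes untestable")
    return(res)
  }
  if (is.null(factors)) factors <- tmm_factors(counts)
  offset <- log(factors)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, groups)
  phi <- dispersions$dispersion
  testable <- !dispersions$untestable
  mask <- !is.na(counts)
  # a gene also needs >= 1 observed sample in each caste
  testable <- testable &
    rowSums(mask[, groups == "queen", drop = FALSE]) >= 1 &
    rowSums(mask[, groups == "worker", drop = FALSE]) >= 1

  y <- counts[testable, , drop = FALSE]
  ph <- phi[testable]
  null_fit <- nb_fit_intercept(y, offset, ph)
  iq <- groups == "queen"
  fit_q <- nb_fit_intercept(y[, iq, drop = FALSE], offset[iq], ph)
  fit_w <- nb_fit_intercept(y[, !iq, drop = FALSE], offset[!iq], ph)
  lrt <- pmax(2 * (fit_q$loglik + fit_w$loglik - null_fit$loglik), 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  res$logFC[testable] <- (fit_q$b - fit_w$b) / log(2)
  res$p[testable] <- p
  res$untestable <- !testable
  res$q <- bh_fdr(res$p)
  sig <- !is.na(res$q) & res$q < alpha
  res$direction[sig] <- ifelse(res$logFC[sig] > 0, "queen", "worker")
  res
}
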