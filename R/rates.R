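# Regression of evolutionary rate (dN/dS) on module caste association,
# connectivity and expression.

#' Log-transform rate-analysis variables
#'
#' Natural-log transform of omega (dN/dS), connectivity and expression (the
#' three are strongly right-skewed); zeros are offset by `offset` before
#' the log. `method = "none"` returns the table unchanged.
#'
#' @param records data.frame with columns omega, expression, connectivity
#'   (and any others, passed through).
#' @param method "log" (default) or "none".
#' @param offset added to zero values before the log (default 1e-6).
#' @return the table with transformed columns; attribute `"transform"`
#'   records the method.
#' @export
transform_variables <- function(records, method = c("log", "none"),
                                offset = 1e-6) {
  method <- match.arg(method)
  if (method == "log") {
    for (col in intersect(c("omega", "expression", "connectivity"),
                          names(records))) {
      x <- records[[col]]
      if (any(x < 0, na.rm = TRUE)) stop(col, " has negative values")
      records[[col]] <- log(ifelse(x == 0, offset, x))
    }
  }
  attr(records, "transform") <- method
  records
}

# Internal: fit one lm and return its coefficients.
rate_lm <- function(formula, data) lm(formula, data = data)

#' Bootstrap a Gaussian rate model
#'
#' Nonparametric case resampling of OGG rows with percentile 95% CIs on
#' every coefficient; a term is flagged significant when its CI excludes 0.
#'
#' @param records transformed rate table (see [transform_variables()]).
#' @param formula model formula on the table's columns.
#' @param n_boot bootstrap pseudoreplicates (default 1000).
#' @param seed RNG seed.
#' @return object of class `rate_glm_fit`: data.frame `coefficients`
#'   (term, estimate, ci_lower, ci_upper, significant) plus `n_boot`,
#'   `formula`.
#' @export
bootstrap_glm <- function(records, formula, n_boot = 1000, seed = 1L) {
  fit <- rate_lm(formula, records)
  est <- coef(fit)
  boots <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(records), replace = TRUE)
      coef(rate_lm(formula, records[idx, , drop = FALSE]))
    }, numeric(length(est)))
  })
  boots <- matrix(boots, nrow = length(est),
                  dimnames = list(names(est), NULL))
  ci <- apply(boots, 1, quantile, c(0.025, 0.975))
  out <- data.frame(term = names(est), estimate = est,
                    ci_lower = ci[1, ], ci_upper = ci[2, ],
                    significant = ci[1, ] > 0 | ci[2, ] < 0,
                    row.names = NULL)
  structure(list(coefficients = out, n_boot = n_boot, formula = formula),
            class = "rate_glm_fit")
}

#' The three evolutionary-rate regression models
#'
#' Gaussian linear models on log-transformed variables, each with bootstrap
#' percentile CIs: (1) omega ~ caste association (NTA reference, treatment
#' coding), (2) omega ~ expression + connectivity, (3) the full model
#' omega ~ connectivity * caste + expression * caste; plus the auxiliary
#' fits connectivity ~ caste and expression ~ caste.
#'
#' @param records data.frame with columns omega, expression, connectivity
#'   and caste_label (factor or character; "NTA" is the reference level).
#' @param n_boot bootstrap pseudoreplicates per model (default 1000).
#' @param seed RNG seed.
#' @param transform transformation applied first (default "log").
#' @return named list of `rate_glm_fit` objects: caste, network, full,
#'   connectivity_caste, expression_caste (caste models NULL with a warning
#'   when fewer than two caste levels are present).
#' @export
fit_rate_models <- function(records, n_boot = 1000, seed = 1L,
                            transform = "log") {
  records <- transform_variables(records, method = transform)
  lv <- unique(as.character(records$caste_label))
  records$caste_label <- factor(records$caste_label,
                                levels = c("NTA", setdiff(sort(lv), "NTA")))
  has_caste <- nlevels(records$caste_label) >= 2
  out <- list(caste = NULL, network = NULL, full = NULL,
              connectivity_caste = NULL, expression_caste = NULL)
  if (has_caste) {
    out$caste <- bootstrap_glm(records, omega ~ caste_label, n_boot,
                               seed = seed + 1)
    out$connectivity_caste <- bootstrap_glm(records,
                                            connectivity ~ caste_label,
                                            n_boot, seed = seed + 2)
    out$expression_caste <- bootstrap_glm(records, expression ~ caste_label,
                                          n_boot, seed = seed + 3)
  } else {
    warning("fewer than two caste levels; caste models skipped")
  }
  out$network <- bootstrap_glm(records, omega ~ expression + connectivity,
                               n_boot, seed = seed + 4)
  if (has_caste)
    out$full <- bootstrap_glm(records,
                              omega ~ connectivity * caste_label +
                                expression * caste_label,
                              n_boot, seed = seed + 5)
  out
}
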