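test_that("phylogenetic correlation matrices follow shared path lengths", {
  # star tree: identity
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(phylo_covariance(star), diag(4), ignore_attr = TRUE)
  # sisters diverging at 90% of the height share 0.9
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.9,C:1);")
  C <- phylo_covariance(tr)
  expect_equal(C["A", "B"], 0.9)
  expect_equal(C["A", "C"], 0)
  expect_equal(diag(C), c(A = 1, B = 1, C = 1))
  # PSD on random trees
  for (s in 1:5) {
    Cs <- phylo_covariance(simulate_tree(12, s))
    expect_gte(min(eigen(Cs, symmetric = TRUE)$values), -1e-9)
  }
  # non-ultrametric trees rejected
  bad <- ape::read.tree(text = "((A:0.2,B:0.1):0.9,C:1);")
  expect_error(phylo_covariance(bad), "ultrametric")
})

test_that("the Gibbs sampler matches OLS and GLS closed forms", {
  fx <- make_design()
  design <- fx$design; C <- fx$C
  n <- nrow(design)
  set.seed(5)
  u <- drop(rnorm(16) %*% chol(C)) * 0.5
  y <- 1.0 * (design$caste == "queen") +
    u[match(design$species, rownames(C))] + rnorm(n, 0, 0.5)
  X <- cbind(1, design$caste == "queen", design$worker_sterility,
             design$queen_number, design$invasiveness)

  # sigma_p = 0 degenerates to Bayesian OLS
  fit0 <- fit_phylo_mixed_model(y, design, C, sigma_p = 0, seed = 12)
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  mc_se <- apply(fit0$chain, 2, sd) / sqrt(fit0$summary$ess)
  expect_true(all(abs(fit0$summary$post_mean - ols) < 4 * mc_se))

  # fixed variance ratio matches the GLS estimator
  Z <- outer(design$species, rownames(C), "==") * 1
  V <- 0.25 * Z %*% C %*% t(Z) + 0.25 * diag(n)
  gls <- drop(solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y)))
  fitg <- fit_phylo_mixed_model(y, design, C, sigma_p = 0.5, sigma_e = 0.5,
                                seed = 13)
  mc_se_g <- apply(fitg$chain, 2, sd) / sqrt(fitg$summary$ess)
  expect_true(all(abs(fitg$summary$post_mean - gls) < 4 * mc_se_g))

  # determinism and cross-seed agreement
  fit_a <- fit_phylo_mixed_model(y, design, C, seed = 21)
  expect_identical(fit_a$summary,
                   fit_phylo_mixed_model(y, design, C, seed = 21)$summary)
  fit_b <- fit_phylo_mixed_model(y, design, C, seed = 22)
  se_ab <- sqrt((apply(fit_a$chain, 2, sd) / sqrt(fit_a$summary$ess))^2 +
                  (apply(fit_b$chain, 2, sd) / sqrt(fit_b$summary$ess))^2)
  expect_true(all(abs(fit_a$summary$post_mean - fit_b$summary$post_mean) <
                    4 * se_ab))
  expect_true(all(fit_a$summary$pMCMC > 0 & fit_a$summary$pMCMC <= 1))
  expect_true(all(fit_a$summary$ci_lower <= fit_a$summary$post_mean &
                    fit_a$summary$post_mean <= fit_a$summary$ci_upper))
})

test_that("module classification applies the pMCMC sign rule", {
  fake_fit <- function(terms, means, ps) {
    list(summary = data.frame(term = terms, post_mean = means,
                              ci_lower = means - 1, ci_upper = means + 1,
                              pMCMC = ps, ess = 1000))
  }
  terms <- c("intercept", "caste", "worker_sterility", "queen_number",
             "invasiveness")
  fits <- list(
    ME1 = fake_fit(terms, c(0, 2, 0.5, -1, 0.1), c(1, 0.001, 0.5, 0.01, 0.9)),
    ME2 = fake_fit(terms, c(0, -2, 0.5, 1, 0.1), c(1, 0.01, 0.02, 0.2, 0.04)),
    ME3 = fake_fit(terms, c(0, 3, 1, 1, 1), c(1, 0.5, 0.5, 0.5, 0.5)))
  lab <- classify_modules(fits, alpha = 0.05)
  expect_identical(lab$caste, c("queen", "worker", "NTA"))
  expect_identical(lab$worker_sterility, c("NTA", "sterile", "NTA"))
  expect_identical(lab$queen_number, c("single", "NTA", "NTA"))
  expect_identical(lab$invasiveness, c("NTA", "invasive", "NTA"))
})

test_that("caste recoding flips queen and worker labels exactly", {
  fx <- make_design(8, 3)
  design <- fx$design; C <- fx$C
  set.seed(9)
  y <- 1.5 * (design$caste == "queen") + rnorm(nrow(design), 0, 0.5)
  fit_q <- fit_phylo_mixed_model(y, design, C, seed = 31)
  design_flipped <- design
  design_flipped$caste <- ifelse(design$caste == "queen", "worker", "queen")
  fit_w <- fit_phylo_mixed_model(y, design_flipped, C, seed = 31)
  lq <- classify_modules(list(ME1 = fit_q))$caste
  lw <- classify_modules(list(ME1 = fit_w))$caste
  expect_identical(lq, "queen")
  expect_identical(lw, "worker")
})

test_that("null eigengenes are called non-trait-associated at rate alpha", {
  fx <- make_design(8, 3)
  design <- fx$design; C <- fx$C
  n <- nrow(design)
  calls <- vapply(1:200, function(r) {
    set.seed(4000 + r)
    y <- rnorm(n)
    f <- fit_phylo_mixed_model(y, design, C, n_iter = 6000, burn_in = 1000,
                               thin = 5, seed = 5000 + r, ess_floor = 0)
    f$summary$pMCMC[f$summary$term == "caste"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(calls) - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
})
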