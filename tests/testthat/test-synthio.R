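test_that("simulated trees are ultrametric pure-birth trees of height 1", {
  tr2 <- simulate_tree(2, seed = 1)
  d2 <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(d2, c(1, 1))

  tr <- simulate_tree(16, seed = 1)
  expect_length(tr$tip.label, 16)
  depths <- ape::node.depth.edgelength(tr)[1:16]
  expect_true(max(abs(depths - 1)) < 1e-9)

  expect_identical(ape::write.tree(simulate_tree(16, seed = 7)),
                   ape::write.tree(simulate_tree(16, seed = 7)))
  expect_error(simulate_tree(1), "n_species")
})

test_that("binary traits follow the two-state chain limits", {
  tree <- simulate_tree(8, 3)
  # rate 0: every tip inherits the root state
  t0 <- simulate_species_traits(tree, switch_rate = 0, seed = 5)
  for (col in c("worker_sterility", "queen_number", "invasiveness"))
    expect_length(unique(t0[[col]]), 1)
  expect_error(simulate_species_traits(tree, switch_rate = -1))
  # determinism
  expect_identical(simulate_species_traits(tree, 1, 11),
                   simulate_species_traits(tree, 1, 11))
  # saturated rate: tips ~ iid Bernoulli(0.5); sister tips uncorrelated
  st <- vapply(1:500, function(s)
    simulate_species_traits(tree, 1e6, s)$worker_sterility, integer(8))
  expect_true(all(abs(rowMeans(st) - 0.5) < 0.08))
  # an actual sister pair from the topology
  tips <- 1:8
  anc <- tree$edge[, 1][match(tips, tree$edge[, 2])]
  sis <- which(duplicated(anc) | duplicated(anc, fromLast = TRUE))[1:2]
  expect_lt(abs(cor(st[sis[1], ], st[sis[2], ])), 0.15)
})

test_that("expression generator matches its null and planted contracts", {
  tree <- simulate_tree(16, 1)
  traits <- simulate_species_traits(tree, 1, 2)
  # sample arithmetic: 16 species x 2 castes x 3 replicates
  cfg <- sim_config(n_oggs = 100, n_modules = 2,
                    module_size_range = c(20, 30), seed = 4)
  sim <- simulate_expression(cfg, tree, traits)
  expect_identical(ncol(sim$counts), 96L)
  expect_identical(nrow(sim$samples), 96L)

  # null config: exchangeable genes, correlations near zero
  cfg0 <- sim_config(n_oggs = 200, n_modules = 2, caste_effect_sd = 0,
                     trait_effect_sd = 0, phylo_sd = 0, loading = 0,
                     dropout_prob = 0, multi_transcript_frac = 0, seed = 3)
  sim0 <- simulate_expression(cfg0, tree, traits)
  cc <- cor(t(log2_cpm(sim0$counts)))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.1)

  # planted module with loading 1, factor noise 0.1: the analytic variance
  # ratio predicts the mean within-module correlation
  cfgm <- sim_config(n_oggs = 400, n_modules = 3, factor_noise_sd = 0.1,
                     loading = 1, dropout_prob = 0,
                     multi_transcript_frac = 0, seed = 7)
  simm <- simulate_expression(cfgm, tree, traits)
  lc <- log2_cpm(simm$counts)
  for (m in 1:3) {
    idx <- simm$truth$module == m
    v_f <- var(simm$truth$factors[m, ]) / log(2)^2
    phi <- simm$truth$dispersion[idx]
    mu <- rowMeans(2^lc[idx, ] - 1)
    v_noise <- mean(phi + 1 / pmax(mu, 1)) / log(2)^2
    predicted <- v_f / (v_f + v_noise)
    ccm <- cor(t(lc[idx, ]))
    observed <- mean(ccm[upper.tri(ccm)])
    expect_lt(abs(observed - predicted), 0.12)
    if (predicted > 0.85) expect_gt(observed, 0.8)
  }

  # determinism
  sim_b <- simulate_expression(cfgm, tree, traits)
  expect_identical(sim_b$counts, simm$counts)

  # dropout blanks whole species columns
  cfgd <- sim_config(n_oggs = 150, n_modules = 0, dropout_prob = 0.3,
                     multi_transcript_frac = 0, seed = 9)
  simd <- simulate_expression(cfgd, tree, traits)
  for (sp in tree$tip.label[1:4]) {
    cols <- simd$samples$species == sp
    nas <- is.na(simd$counts[, cols, drop = FALSE])
    expect_true(all(rowSums(nas) %in% c(0, sum(cols))))
  }
  expect_error(simulate_expression(cfgd, tree, traits[1:4, ]), "match")
})

test_that("species effects have Brownian covariance proportional to C", {
  tree <- simulate_tree(6, 2)
  traits <- simulate_species_traits(tree, 1, 2)
  C <- phylo_covariance(tree)
  cfg <- sim_config(n_species = 6, n_oggs = 500, n_modules = 500,
                    module_size_range = c(1, 1), phylo_sd = 1,
                    caste_effect_sd = 0, trait_effect_sd = 0,
                    dropout_prob = 0, multi_transcript_frac = 0, seed = 1)
  u <- rbind(simulate_expression(cfg, tree, traits)$truth$species_effects,
             simulate_expression(sim_config(
               n_species = 6, n_oggs = 500, n_modules = 500,
               module_size_range = c(1, 1), phylo_sd = 1,
               caste_effect_sd = 0, trait_effect_sd = 0, dropout_prob = 0,
               multi_transcript_frac = 0, seed = 2),
               tree, traits)$truth$species_effects)
  emp <- cov(u)  # 1000 draws
  mc_se <- sqrt((1 + C^2) / nrow(u))
  expect_true(all(abs(emp - C) <= 3 * mc_se))
})

test_that("omega generator follows its log-linear model", {
  set.seed(99)
  n <- 2000
  truth <- list(ogg = sprintf("OGG%05d", 1:n),
                caste_associated = rbinom(n, 1, 0.4))
  conn <- exp(rnorm(n, 2, 1)); expr <- exp(rnorm(n, 4, 1))
  # all coefficients zero, no noise: omega = exp(intercept) everywhere
  cz <- c(intercept = -1, expr = 0, conn = 0, caste = 0, conn_caste = 0,
          expr_caste = 0)
  tz <- simulate_omega(truth, conn, expr, cz, log_sd = 0, seed = 1)
  expect_equal(tz$omega, rep(exp(-1), n))
  # single slope recovered by OLS within 2 SE
  cs <- c(intercept = 0, expr = 0, conn = -0.5, caste = 0, conn_caste = 0,
          expr_caste = 0)
  ts <- simulate_omega(truth, conn, expr, cs, log_sd = 0.5, seed = 2)
  fit <- summary(lm(log(omega) ~ log(connectivity), data = ts))
  expect_lt(abs(fit$coefficients[2, 1] + 0.5),
            2 * fit$coefficients[2, 2])
  # determinism and input validation
  expect_identical(simulate_omega(truth, conn, expr, cs, 0.5, 3),
                   simulate_omega(truth, conn, expr, cs, 0.5, 3))
  expect_error(simulate_omega(truth, c(-1, conn[-1]), expr, cs, 0.5, 1),
               "connectivity")
  expect_error(simulate_omega(truth, conn, c(0, expr[-1]), cs, 0.5, 1),
               "expression")
})

test_that("annotation generator covers its trivial contracts", {
  expect_identical(nrow(simulate_annotations(10, 5, 0)), 0L)
  a1 <- simulate_annotations(10, 1, 1, seed = 1)
  expect_identical(unique(a1$term), "TERM0001")
  expect_identical(simulate_annotations(20, 10, 3, seed = 2),
                   simulate_annotations(20, 10, 3, seed = 2))
})

test_that("simulation round-trips through plain-text files", {
  tree <- simulate_tree(4, 1)
  traits <- simulate_species_traits(tree, 1, 2)
  cfg <- sim_config(n_species = 4, n_oggs = 30, n_modules = 1,
                    module_size_range = c(5, 10), seed = 3)
  sim <- simulate_expression(cfg, tree, traits)
  dir <- tempfile()
  write_simulation(sim, tree, traits, dir)
  cts <- read.table(file.path(dir, "counts.tsv"), header = TRUE, sep = "\t",
                    check.names = FALSE)
  expect_identical(nrow(cts), nrow(sim$counts))
  m <- as.matrix(cts[, -1])
  rownames(m) <- cts$transcript
  expect_equal(m, sim$counts, ignore_attr = TRUE)
  tr2 <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_identical(sort(tr2$tip.label), sort(tree$tip.label))
})
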