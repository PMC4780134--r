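test_that("adjacency follows the soft-threshold formula", {
  set.seed(1)
  v <- rnorm(30)
  m <- rbind(g1 = v, g2 = v, g3 = -v, g4 = rnorm(30))
  a <- adjacency(m, power = 8)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 1)  # unsigned: anti-correlation same strength
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(a, t(a))
  # cor 0.5 at beta 8
  x <- rnorm(1e4); y <- 0.5 * x + sqrt(0.75) * rnorm(1e4)
  r <- cor(x, y)
  a2 <- adjacency(rbind(a = x, b = y), power = 8)
  expect_equal(a2["a", "b"], abs(r)^8)
  expect_equal(0.5^8, 0.00390625)
  # signed mode
  asg <- adjacency(m, power = 2, mode = "signed")
  expect_lt(asg["g1", "g3"], asg["g1", "g2"])
})

test_that("TOM matches hand values and the brute-force triple loop", {
  # two genes connected only to each other, a = 0.5
  a <- diag(2); a[1, 2] <- a[2, 1] <- 0.5
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 0.5)
  # complete 3-gene graph with unit weights
  a3 <- matrix(1, 3, 3)
  expect_true(all(topological_overlap(a3) == 1))
  # no edges
  a0 <- diag(4)
  expect_equal(sum(topological_overlap(a0)) , 4)

  # brute-force oracle on random adjacencies up to n = 50
  for (n in c(10, 30, 50)) {
    set.seed(n)
    r <- matrix(runif(n * n), n)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- topological_overlap(a)
    oracle <- matrix(0, n, n)
    k <- rowSums(a) - 1
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) { oracle[i, j] <- 1; next }
      s <- 0
      for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      oracle[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    expect_lt(max(abs(tom - oracle)), 1e-10)
  }
})

test_that("soft-threshold selection finds scale-free regimes", {
  # factor model with uniform loadings gives a power-law connectivity tail
  set.seed(42)
  n <- 300; ns <- 2000
  l <- runif(n, 0.05, 0.95)
  x <- outer(l, rnorm(ns)) + matrix(rnorm(n * ns), n) * sqrt(1 - l^2)
  pst <- pick_soft_threshold(x, candidate_powers = c(2, 4, 6, 8),
                             r2_target = 0.9)
  expect_gte(max(pst$fit_table$r2_signed, na.rm = TRUE), 0.95)
  # mean connectivity strictly decreases with the power
  expect_true(all(diff(pst$fit_table$mean_k) < 0))
  # when no power fits, the best one is returned with a warning
  set.seed(1)
  xb <- matrix(rnorm(40 * 30), 40, 30)
  expect_warning(pb <- pick_soft_threshold(xb, candidate_powers = 1:2,
                                           r2_target = 0.999),
                 "best-fitting")
  expect_true(pb$power %in% 1:2)
})

test_that("module detection recovers planted blocks and ignores noise", {
  pb <- planted_blocks(40, 3, 60, rho = 0.9, seed = 2)
  tom <- topological_overlap(adjacency(pb$x, 8))
  lab <- cluster_modules(tom, min_module_size = 30)
  expect_identical(length(unique(lab[lab > 0])), 3L)
  expect_equal(adjusted_rand_index(lab, pb$truth), 1)
  # structureless data: no modules in >= 90% of 20 seeds
  clean <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(300 * 40), 300, 40,
                dimnames = list(paste0("g", 1:300), NULL))
    all(cluster_modules(topological_overlap(adjacency(x, 8)),
                        min_module_size = 30) == 0)
  }, logical(1))
  expect_gte(mean(clean), 0.9)
  # min size larger than n: everything unassigned
  lab2 <- cluster_modules(tom, min_module_size = nrow(pb$x) + 1)
  expect_true(all(lab2 == 0))
})

test_that("eigengenes equal the first principal component", {
  # identical profiles: variance explained 1
  set.seed(3)
  v <- rnorm(20)
  x <- rbind(g1 = v, g2 = v, g3 = v)
  eg <- module_eigengenes(x, c(1, 1, 1))
  expect_equal(unname(eg$var_explained), 1)
  expect_equal(sum(eg$eigengenes[1, ]^2), 1)
  expect_gt(cor(eg$eigengenes[1, ], v), 0.999)
  # two anti-correlated genes: variance explained 1, cor +1 / -1
  x2 <- rbind(g1 = v, g2 = -v)
  eg2 <- module_eigengenes(x2, c(1, 1))
  expect_equal(unname(eg2$var_explained), 1)
  cors <- cor(eg2$eigengenes[1, ], t(x2))
  expect_equal(sort(as.numeric(cors)), c(-1, 1))
  # dense SVD oracle on a realistic module
  pb <- planted_blocks(30, 1, 40, rho = 0.8, seed = 4)
  eg3 <- module_eigengenes(pb$x, rep(1, 30))
  xs <- t(scale(t(pb$x)))
  ev <- eigen(crossprod(xs))
  oracle <- ev$vectors[, 1]
  if (mean(cor(oracle, t(xs))) < 0) oracle <- -oracle
  expect_lt(max(abs(eg3$eigengenes[1, ] - oracle)), 1e-8)
  expect_equal(unname(eg3$var_explained),
               ev$values[1] / sum(ev$values), tolerance = 1e-8)
})

test_that("module merging applies the eigengene dissimilarity rule", {
  make_pair <- function(rho, seed) {
    set.seed(seed)
    ns <- 200
    f1 <- rnorm(ns)
    f2 <- rho * f1 + sqrt(1 - rho^2) * rnorm(ns)
    x <- rbind(outer(rep(1, 30), f1), outer(rep(1, 30), f2)) +
      matrix(rnorm(60 * ns), 60) * 0.05
    rownames(x) <- paste0("g", 1:60)
    x
  }
  lab0 <- rep(1:2, each = 30)
  # eigengene cor ~0.9: merged
  xm <- make_pair(0.9, 1)
  expect_identical(length(unique(merge_modules(xm, lab0, 0.2))), 1L)
  # eigengene cor ~0.7: kept apart
  xk <- make_pair(0.7, 2)
  expect_identical(length(unique(merge_modules(xk, lab0, 0.2))), 2L)
  # chain merging reaches the same partition regardless of input order
  set.seed(5)
  ns <- 300
  f1 <- rnorm(ns)
  f2 <- 0.93 * f1 + sqrt(1 - 0.93^2) * rnorm(ns)
  f3 <- 0.88 * f2 + sqrt(1 - 0.88^2) * rnorm(ns)
  x <- rbind(outer(rep(1, 30), f1), outer(rep(1, 30), f2),
             outer(rep(1, 30), f3)) + matrix(rnorm(90 * ns), 90) * 0.05
  rownames(x) <- paste0("g", 1:90)
  lab <- rep(1:3, each = 30)
  ref <- merge_modules(x, lab, 0.2)
  for (perm_seed in 1:3) {
    set.seed(perm_seed)
    ord <- sample(90)
    got <- merge_modules(x[ord, ], lab[ord], 0.2)
    expect_equal(adjusted_rand_index(got, ref[ord]), 1)
  }
})

test_that("connectivity satisfies the handshake identity", {
  # complete unit graph
  ac <- matrix(1, 5, 5)
  rownames(ac) <- colnames(ac) <- paste0("g", 1:5)
  ct <- connectivity(ac, rep(1, 5))
  expect_true(all(ct$kTotal == 4))
  # isolated gene
  ai <- diag(3)
  rownames(ai) <- colnames(ai) <- paste0("g", 1:3)
  expect_true(all(connectivity(ai, rep(0, 3))$kTotal == 0))
  # handshake: within-module connectivity sums to twice the edge weights
  for (s in 1:5) {
    set.seed(s)
    n <- 20
    r <- matrix(runif(n * n), n)
    a <- (r + t(r)) / 2; diag(a) <- 1
    rownames(a) <- colnames(a) <- paste0("g", 1:n)
    mod <- sample(0:2, n, replace = TRUE)
    ct <- connectivity(a, mod)
    for (m in 1:2) {
      idx <- mod == m
      am <- a[idx, idx]; diag(am) <- 0
      expect_equal(sum(ct$kWithin[idx]), sum(am))
      expect_true(all(ct$kWithin[idx] <= ct$kTotal[idx] + 1e-12))
    }
  }
})
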