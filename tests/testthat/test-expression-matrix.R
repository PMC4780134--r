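test_that("TMM factors match the trimmed weighted-mean formula", {
  set.seed(1)
  a <- rpois(500, 100)
  # identical libraries
  expect_equal(unname(tmm_factors(cbind(A = a, B = a))), c(1, 1))
  # doubled library: factors (1/sqrt(2), sqrt(2)) after renormalization
  f <- tmm_factors(cbind(A = a, B = 2L * a))
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # 4 NB libraries, no DE: factors near 1 over 20 seeds
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(rnbinom(2000, mu = 50, size = 5), 500, 4)
    expect_true(all(tmm_factors(m) > 0.9 & tmm_factors(m) < 1.1))
  }
  expect_error(tmm_factors(cbind(A = a, B = 0L * a)), "B")
})

test_that("TMM agrees with the edgeR implementation up to the depth
           convention", {
  skip_if_not_installed("edgeR")
  set.seed(2)
  m <- matrix(rnbinom(3000, mu = exp(rnorm(750, 4, 1)), size = 5), 750, 4)
  m[1:50, 1] <- m[1:50, 1] * 4
  fe <- edgeR::calcNormFactors(m, refColumn = 2)
  fm <- tmm_factors(m, reference = 2)
  N <- colSums(m)
  # our factor absorbs depth: factor = edgeR factor * relative depth
  expect_equal(unname(fm), unname(fe * N / exp(mean(log(N)))),
               tolerance = 1e-10)
})

test_that("normalization preserves within-sample rank order", {
  set.seed(3)
  m <- matrix(rnbinom(600, mu = exp(rnorm(150, 4, 1)), size = 5), 150, 4,
              dimnames = list(paste0("g", 1:150), paste0("s", 1:4)))
  lc <- log2_cpm(m)
  for (j in 1:4) expect_identical(order(m[, j]), order(lc[, j]))
})

test_that("low-count filter keeps genes passing in at least one caste", {
  set.seed(4)
  m <- matrix(rpois(40, 20), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_identical(low_count_filter(m, 0, 2), m)
  m2 <- m; m2[3, ] <- 0L
  expect_false("g3" %in% rownames(low_count_filter(m2, 1, 1)))
  # hand-enumerated toy: 3 genes below threshold everywhere
  m3 <- m; m3[c(2, 5, 9), ] <- 1L
  kept <- low_count_filter(m3, 5, 2, groups = c("q", "q", "w", "w"))
  expect_identical(nrow(kept), 7L)
  expect_false(any(c("g2", "g5", "g9") %in% rownames(kept)))
  # group rule: enough in one caste suffices
  m4 <- m; m4[1, 1:2] <- 50L; m4[1, 3:4] <- 0L
  expect_true("g1" %in%
                rownames(low_count_filter(m4, 10, 2,
                                          groups = c("q", "q", "w", "w"))))
})

test_that("transcript aggregation averages within OGG and keeps missing", {
  m <- matrix(c(4, 6, 2, 8, 10, 12), 3, 2, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  map <- data.frame(transcript = c("t1", "t2", "t3"),
                    ogg = c("O1", "O1", "O2"))
  ag <- aggregate_to_ogg(m, map)
  expect_equal(ag["O1", ], c(s1 = (4 + 2) / 2, s2 = (6 + 8) / 2))
  expect_equal(ag["O2", ], c(s1 = 10, s2 = 12))
  # single transcript per OGG passes through
  map1 <- data.frame(transcript = c("t1", "t3"), ogg = c("Oa", "Ob"))
  expect_equal(unname(aggregate_to_ogg(m, map1)), unname(m[c(1, 3), ]))
  # missing species stays missing
  mna <- m; mna["t3", "s2"] <- NA
  expect_true(is.na(aggregate_to_ogg(mna, map)["O2", "s2"]))
  expect_error(aggregate_to_ogg(m, data.frame(transcript = "nope",
                                              ogg = "O9")), "nope")
})

test_that("OGG filter removes missing/constant rows with reasons", {
  m <- rbind(const = rep(5, 10), ok = rnorm(10),
             holey = c(rep(NA, 6), rnorm(4)))
  colnames(m) <- paste0("s", 1:10)
  fl <- filter_oggs(m, max_missing_fraction = 0.5)
  expect_identical(rownames(fl$matrix), "ok")
  expect_setequal(fl$removed$ogg, c("const", "holey"))
  expect_identical(fl$removed$reason[fl$removed$ogg == "const"],
                   "zero variance")
  expect_identical(fl$removed$reason[fl$removed$ogg == "holey"],
                   "too many missing samples")
  # idempotence and no false removals
  fl2 <- filter_oggs(fl$matrix, 0.5)
  expect_identical(fl2$matrix, fl$matrix)
  expect_identical(nrow(fl2$removed), 0L)
})

test_that("outlier detection flags shifted samples and spares nulls", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    m <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(NULL, paste0("s", 1:20)))
    length(detect_outlier_samples(m)) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  set.seed(3)
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(NULL, paste0("s", 1:20)))
  m[, 7] <- m[, 7] + 10
  expect_identical(as.character(detect_outlier_samples(m)), "s7")
  expect_error(detect_outlier_samples(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("MDS embeds correlation distances exactly for small cases", {
  # identical samples collapse to one point
  set.seed(1)
  v <- rnorm(100)
  m <- cbind(a = v, b = v, c = rnorm(100))
  co <- mds_coordinates(m)
  expect_lt(sqrt(sum((co["a", ] - co["b", ])^2)), 1e-6)
  # three samples: recovered distances equal the input distances
  for (s in 1:5) {
    set.seed(s)
    m3 <- matrix(rnorm(200 * 3), 200, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
    co3 <- mds_coordinates(m3)
    expect_equal(as.matrix(dist(co3)), 1 - cor(m3), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # matches an independent double-centering oracle up to reflection
  set.seed(2)
  m6 <- matrix(rnorm(100 * 6), 100, 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  D <- 1 - cor(m6)
  J <- diag(6) - 1 / 6
  B <- -0.5 * J %*% D^2 %*% J
  e <- eigen(B)
  oracle <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  mine <- mds_coordinates(m6)
  for (k in 1:2)
    expect_lt(min(max(abs(mine[, k] - oracle[, k])),
                  max(abs(mine[, k] + oracle[, k]))), 1e-6)
})
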