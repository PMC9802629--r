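twoClouds <- function(n1 = 10, n2 = 10, gap = 10, f = 3, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(n1 * f, 0, 0.3), n1, f),
        matrix(rnorm(n2 * f, gap, 0.3), n2, f))
}

test_that("k-means partitions separable data and k=1 is trivial", {
  X <- twoClouds()
  labs <- kmeansPartition(X, 2, seed = 1)
  expect_equal(length(unique(labs[1:10])), 1)
  expect_equal(length(unique(labs[11:20])), 1)
  expect_false(labs[1] == labs[11])

  labs1 <- kmeansPartition(X, 1, seed = 1)
  expect_true(all(labs1 == 1L))

  expect_error(kmeansPartition(X[0, , drop = FALSE], 2), "empty")
  expect_error(kmeansPartition(X, 30), "exceed")
})

test_that("k-means WCSS attains the exhaustive 2-partition minimum", {
  set.seed(7)
  X <- matrix(rnorm(8 * 2), 8, 2)
  labs <- kmeansPartition(X, 2, seed = 3, restarts = 10)
  expect_equal(attr(labs, "wcss"), bruteForceWcss2(X), tolerance = 1e-8)
})

test_that("consensus matrix matches a direct recount of the resamples", {
  set.seed(2)
  X <- matrix(rnorm(6 * 2), 6, 2)
  scheme <- resampleScheme(nResamples = 3, subsampleFraction = 0.8,
                           baseSeed = 10)
  M <- suppressWarnings(consensusMatrix(X, 2, scheme))

  # replay the seed ladder, store the three partitions, recount by hand
  nSub <- ceiling(0.8 * 6)
  together <- sampled <- matrix(0, 6, 6)
  for (r in 1:3) {
    set.seed(10 + r)
    idx <- sample.int(6, nSub)
    labs <- kmeansPartition(X[idx, , drop = FALSE], 2, seed = 10 + r)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      sampled[idx[a], idx[b]] <- sampled[idx[a], idx[b]] + 1
      if (labs[a] == labs[b])
        together[idx[a], idx[b]] <- together[idx[a], idx[b]] + 1
    }
  }
  expected <- ifelse(sampled > 0, together / sampled, 0)
  diag(expected) <- 1
  expect_equal(unname(M[, ]), expected, tolerance = 1e-12)
})

test_that("consensus matrix is symmetric in [0,1]; separable clouds polarize", {
  X <- twoClouds(8, 8)
  M <- consensusMatrix(X, 2, resampleScheme(20, 0.8, 5))
  expect_lt(max(abs(M - t(M))), 1e-12)
  expect_true(all(M >= 0 & M <= 1))
  within <- c(M[1:8, 1:8][upper.tri(M[1:8, 1:8])],
              M[9:16, 9:16][upper.tri(M[9:16, 9:16])])
  across <- M[1:8, 9:16]
  expect_true(all(within == 1))
  expect_true(all(across == 0))

  # exact duplicates always co-cluster when co-sampled
  Xd <- rbind(X, X[1, ])
  Md <- consensusMatrix(Xd, 2, resampleScheme(20, 0.9, 5))
  cs <- attr(Md, "cosampled")
  if (cs[1, 17] > 0) expect_equal(Md[1, 17], 1)
})

test_that("CDF area matches analytic and numeric-integration oracles", {
  # 4 items, perfect 2-clustering: two within-pairs at 1, four across at 0
  M <- matrix(0, 4, 4); diag(M) <- 1
  M[1, 2] <- M[2, 1] <- 1; M[3, 4] <- M[4, 3] <- 1
  ca <- cdfArea(M)
  expect_equal(ca$area, 4 / 6)

  M1 <- matrix(1, 4, 4)
  expect_equal(cdfArea(M1)$area, 0)

  set.seed(4)
  R <- matrix(runif(25), 5, 5); R <- (R + t(R)) / 2; diag(R) <- 1
  ca2 <- cdfArea(R)
  grid <- seq(0, 1, length.out = 1e4 + 1)
  x <- R[upper.tri(R)]
  riemann <- mean(vapply(grid[-1], function(u) mean(x <= u), 0))
  expect_equal(ca2$area, riemann, tolerance = 1e-3)

  expect_error(cdfArea(matrix(1, 1, 1)), "at least 2")
})

test_that("delta-area rule selects the last k with a large relative gain", {
  areas <- c(`2` = 0.5)
  areas["3"] <- areas["2"] * 1.30
  areas["4"] <- areas["3"] * 1.25
  areas["5"] <- areas["4"] * 1.02
  areas["6"] <- areas["5"] * 1.01
  sel <- selectK(areas, threshold = 0.10)
  expect_equal(sel$selectedK, 4L)
  expect_equal(unname(sel$deltaAreas["2"]), 0.5)
  expect_equal(unname(sel$deltaAreas["4"]), 0.25, tolerance = 1e-12)

  flat <- c(`2` = 0.05, `3` = 0.051, `4` = 0.0515)
  expect_equal(selectK(flat, 0.10)$selectedK, 2L)

  expect_error(selectK(numeric(0)), "non-empty")
  expect_error(selectK(c(`3` = 0.5, `4` = 0.6)), "starting at 2")
})

test_that("final partition and cluster consensus agree with a recount", {
  X <- twoClouds(8, 8)
  cr <- consensusCluster(X, kRange = 2,
                         scheme = resampleScheme(15, 0.8, 2))
  expect_equal(selectedK(cr), 2L)
  labs <- finalLabels(cr)
  expect_true(all(cr@clusterConsensus == 1))

  # hand recount of within-cluster consensus on the stored matrix
  M <- consensusMatrixFor(cr, 2)
  for (c in unique(labs)) {
    idx <- which(labs == c)
    sub <- M[idx, idx]
    expect_equal(unname(cr@clusterConsensus[as.character(c)]),
                 mean(sub[upper.tri(sub)]))
  }

  # relabeling invariance: consensus multiset does not depend on label ids
  cc2 <- clusterConsensus(M, 3 - labs)
  expect_equal(sort(unname(cc2)), sort(unname(cr@clusterConsensus)))

  expect_warning(clusterConsensus(M, c(1, rep(2, 15))), "singleton")
})

test_that("doubling the resamples leaves consensus entries stable", {
  fx <- makeFixtureCohort(n = 80, seed = 21)
  M1 <- consensusMatrix(fx$X, 4, resampleScheme(25, 0.8, 1))
  M2 <- consensusMatrix(fx$X, 4, resampleScheme(50, 0.8, 1))
  expect_lt(quantile(abs(M1 - M2), 0.95), 0.1 + 1e-9)
})
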