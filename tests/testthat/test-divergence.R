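labelledMatrix <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(paste0("i", 1:n), paste0("i", 1:n))
  m
}

test_that("dissimilarity categories partition the upper triangle exhaustively", {
  m <- labelledMatrix(5)
  labels <- c("east", "east", "east", "west", "west")
  cats <- categorizeDissimilarities(m, labels)
  expect_equal(lengths(cats$values),
               c(within_east = 3L, within_west = 1L, between = 6L))
  expect_equal(sum(lengths(cats$values)), 5 * 4 / 2)
  # values are the actual matrix entries for their index pairs
  for (nm in names(cats$values)) {
    idx <- as.matrix(cats$pairs[[nm]])
    expect_equal(unname(cats$values[[nm]]), unname(m[idx]))
  }
  expect_error(categorizeDissimilarities(m, rep("east", 5)), "binary")
  expect_error(categorizeDissimilarities(m, c("e", "e", "w", "x", "w")),
               "binary")
})

test_that("a constant dissimilarity matrix gives a null permutation result", {
  m <- matrix(0.4, 10, 10); diag(m) <- 0
  dimnames(m) <- list(1:10, 1:10)
  labels <- rep(c("east", "west"), each = 5)
  r <- permutationTest(m, labels, c("between", "within_east"), B = 199,
                       seed = 3)
  expect_equal(r@observed, 0)
  expect_equal(pValue(r), 1)
})

test_that("strong separation drives the permutation p to its minimum (B+1)^-1", {
  # between-block dissimilarities far exceed both within blocks; n is
  # large enough that label permutations essentially never recreate the
  # observed partition (whose recreation ties the observed statistic)
  n <- 24
  labels <- rep(c("east", "west"), each = n / 2)
  m <- outer(labels, labels, function(a, b) ifelse(a == b, 0.05, 0.9))
  diag(m) <- 0
  dimnames(m) <- list(1:n, 1:n)
  for (cmp in list(c("between", "within_east"), c("between", "within_west"))) {
    r <- permutationTest(m, labels, cmp, B = 499, seed = 11)
    expect_equal(pValue(r), 1 / 500, tolerance = 1e-12)
  }
})

test_that("permutation results are bit-reproducible given the seed", {
  m <- labelledMatrix(14, seed = 6)
  labels <- rep(c("east", "west"), 7)
  a <- permutationTest(m, labels, c("between", "within_west"), B = 299,
                       seed = 42)
  b <- permutationTest(m, labels, c("between", "within_west"), B = 299,
                       seed = 42)
  c <- permutationTest(m, labels, c("between", "within_west"), B = 299,
                       seed = 43)
  expect_identical(pValue(a), pValue(b))
  expect_identical(a@observed, b@observed)
  expect_false(identical(pValue(a), pValue(c)))
})

test_that("permutation p-values are super-uniform under the exchangeable null", {
  # taxa drawn from one distribution: p below alpha at most ~alpha of runs
  set.seed(77)
  ps <- replicate(120, {
    pts <- matrix(rnorm(16 * 3), 16)
    m <- as.matrix(dist(pts)); m <- m / max(m)
    dimnames(m) <- list(1:16, 1:16)
    pValue(permutationTest(m, rep(c("east", "west"), 8),
                           c("between", "within_east"), B = 99,
                           seed = sample.int(1e6, 1)))
  })
  expect_gt(mean(ps <= 0.05), 0.0)   # sanity: not degenerate at 1
  expect_lt(mean(ps <= 0.05), 0.15)  # no gross anti-conservatism
  expect_gt(mean(ps), 0.35)          # roughly uniform bulk
})

test_that("p-value adjustment reproduces hand-computed BH and Bonferroni values", {
  expect_equal(adjustPValues(c(0.01, 0.02, 0.03, 0.04), "benjamini_hochberg"),
               rep(0.04, 4))
  expect_equal(adjustPValues(0.02, "benjamini_hochberg"), 0.02)
  expect_equal(adjustPValues(0.02, "bonferroni"), 0.02)
  expect_equal(adjustPValues(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  # family larger than the list (batch of analyses)
  expect_equal(adjustPValues(0.001, "bonferroni", familySize = 27), 0.027)
  expect_error(adjustPValues(numeric(0)), "empty")
  expect_error(adjustPValues(c(0.5, 0)), "\\(0, 1\\]")
  # BH output is monotone in the sorted order of inputs
  set.seed(1)
  p <- runif(20)
  adj <- adjustPValues(p, "benjamini_hochberg")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p))
})

test_that("the familywise Bonferroni criterion reproduces 0.05/27", {
  expect_equal(signif(bonferroniCriterion(0.05, 3, 9), 3), 0.00185)
})

test_that("the joint ECDF percentile is the right-continuous count fraction", {
  pool <- 1:6
  expect_equal(jointEcdfPercentile(pool, 2), 100 * 2 / 6)
  expect_equal(jointEcdfPercentile(pool, 0.5), 0)
  expect_equal(jointEcdfPercentile(pool, 6), 100)
  expect_equal(jointEcdfPercentile(pool, 2.5), 100 * 2 / 6)  # between points
  expect_error(jointEcdfPercentile(numeric(0), 1), "empty")
  expect_error(jointEcdfPercentile(pool, Inf), "finite")
})

oneFeatureTable <- function(values, taxon) {
  SongFeatureTable(data.frame(`2a` = values, check.names = FALSE),
                   taxon = taxon)
}

test_that("Delta-p reproduces the hand-evaluated one-feature example", {
  a <- oneFeatureTable(c(1, 2, 3), "east")
  b <- oneFeatureTable(c(4, 5, 6), "west")
  r <- deltaP(a, b)
  expect_equal(unname(r@coordinates[, "2a"]), c(100 / 3, 500 / 6))
  expect_equal(deltaPScore(r), 50)
  # identical populations diverge by zero
  expect_equal(deltaPScore(deltaP(a, oneFeatureTable(c(1, 2, 3), "west"))), 0)
  # swap symmetry
  expect_equal(deltaPScore(deltaP(b, a)), 50)
})

test_that("Delta-p is invariant under strictly increasing transforms", {
  set.seed(3)
  a <- randomMixedTable(10, nNumeric = 4, withSlur = FALSE, seed = 13)
  b <- randomMixedTable(12, nNumeric = 4, withSlur = FALSE, seed = 14)
  base <- deltaPScore(deltaP(a, b))
  va <- featureValues(a); vb <- featureValues(b)
  va[[1]] <- log(va[[1]] + 1); vb[[1]] <- log(vb[[1]] + 1)
  va[[2]] <- sqrt(va[[2]]); vb[[2]] <- sqrt(vb[[2]])
  at <- SongFeatureTable(va, taxon = taxonLabels(a))
  bt <- SongFeatureTable(vb, taxon = taxonLabels(b))
  expect_equal(deltaPScore(deltaP(at, bt)), base, tolerance = 1e-12)
})

test_that("Delta-p respects its bound and drops unusable features with notice", {
  a <- randomMixedTable(8, nNumeric = 5, withSlur = TRUE, seed = 23)
  b <- randomMixedTable(9, nNumeric = 5, withSlur = TRUE, seed = 24)
  r <- suppressMessages(deltaP(a, b))
  k <- length(r@featuresUsed)
  expect_lte(deltaPScore(r), 100 * sqrt(k))
  expect_gte(deltaPScore(r), 0)
  # slur excluded by default, included 0/1-encoded on request
  expect_true("8a" %in% r@featuresDropped)
  r2 <- deltaP(a, b, includeCategorical = TRUE)
  expect_true("8a" %in% r2@featuresUsed)
  # a feature observed in only one population is dropped with a message
  va <- featureValues(a); va[["2a"]] <- NA_real_
  a2 <- SongFeatureTable(va, taxon = taxonLabels(a))
  expect_message(r3 <- deltaP(a2, b, includeCategorical = TRUE), "2a")
  expect_false("2a" %in% r3@featuresUsed)
})

test_that("Hedge's g matches hand computation and is antisymmetric", {
  expect_equal(hedgesG(c(1, 2, 3), c(3, 4, 5)), -1.6)
  expect_equal(hedgesG(c(3, 4, 5), c(1, 2, 3)), 1.6)
  expect_equal(hedgesG(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_error(hedgesG(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(hedgesG(1, c(1, 2)), "at least 2")
})

test_that("the two-sample t-test reproduces the pooled hand example", {
  r <- twoSampleT(c(1, 2, 3), c(4, 5, 6), "pooled")
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3), "pooled")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # pooled df is nA + nB - 2
  r2 <- twoSampleT(rnorm(12), rnorm(13), "pooled")
  expect_equal(r2$df, 23)
  w <- twoSampleT(c(1, 2, 3, 9), c(4, 5, 6), "welch")
  expect_lt(w$df, 5)   # Satterthwaite df below pooled df
})

test_that("Spearman correlation handles perfect, reversed, and random ranks", {
  expect_equal(spearmanCorrelation(1:9, (1:9)^2)$rho, 1)
  expect_equal(spearmanCorrelation(1:9, 9:1)$rho, -1)
  set.seed(4)
  x <- rnorm(8); y <- rnorm(8)
  r <- spearmanCorrelation(x, y)
  d <- rank(x) - rank(y)
  expect_equal(r$rho, 1 - 6 * sum(d^2) / (8 * (64 - 1)), tolerance = 1e-12)
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "constant")
})
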