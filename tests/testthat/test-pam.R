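rescaledLineMatrix <- function(points) {
  m <- abs(outer(points, points, "-"))
  m <- m / max(m)
  dimnames(m) <- list(paste0("p", seq_along(points)),
                      paste0("p", seq_along(points)))
  m
}

test_that("PAM recovers the exhaustively optimal medoids on a line", {
  m <- rescaledLineMatrix(c(0, 1, 10, 11))
  fit <- pamCluster(m, k = 2)
  expect_equal(clusterAssignments(fit), c(1L, 1L, 2L, 2L))
  expect_equal(fit@totalCost, pamBruteCost(m, 2))
  # degenerate optimum: lexicographically smallest optimal medoid set
  expect_equal(medoids(fit), c(1L, 3L))
  # the swap heuristic reaches one of the equal-cost optima too
  fitH <- pamCluster(m, k = 2, exactLimit = 0)
  expect_equal(fitH@totalCost, fit@totalCost, tolerance = 1e-12)
  expect_equal(clusterAssignments(fitH), clusterAssignments(fit))
})

test_that("k = 1 returns the row-sum minimiser and no silhouette", {
  m <- rescaledLineMatrix(c(0, 1, 2, 10, 20))
  fit <- pamCluster(m, k = 1)
  expect_equal(medoids(fit), 3L)   # unique row-sum minimiser
  expect_equal(fit@totalCost, min(rowSums(m)))
  expect_length(fit@silhouette, 0)
  expect_true(is.na(avgSilWidth(fit)))
  expect_error(pamCluster(m, k = 5), "k must satisfy")
  expect_error(silhouetteWidths(m, rep(1, 5)), "single cluster")
})

test_that("PAM total cost equals the exhaustive-search optimum on random matrices", {
  set.seed(42)
  for (rep in 1:120) {
    n <- sample(4:8, 1)
    k <- sample(1:3, 1)
    if (k >= n) next
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    dimnames(m) <- list(seq_len(n), seq_len(n))
    fit <- pamCluster(m, k)
    expect_equal(fit@totalCost, pamBruteCost(m, k), tolerance = 1e-12)
    # medoids assigned to themselves; cost consistent with assignment
    expect_equal(clusterAssignments(fit)[medoids(fit)], seq_len(k))
    recomputed <- sum(m[cbind(seq_len(n),
                              medoids(fit)[clusterAssignments(fit)])])
    expect_equal(fit@totalCost, recomputed)
    # the swap heuristic is valid (self-assigned medoids, cost never
    # below the certified optimum) even where it is not optimal
    fitH <- pamCluster(m, k, exactLimit = 0)
    expect_equal(clusterAssignments(fitH)[medoids(fitH)], seq_len(k))
    expect_gte(fitH@totalCost, fit@totalCost - 1e-12)
  }
})

test_that("PAM clustering is invariant under permutation of the input order", {
  set.seed(7)
  n <- 12
  m <- as.matrix(dist(cbind(rnorm(n), rnorm(n))))
  m <- m / max(m)
  dimnames(m) <- list(paste0("i", 1:n), paste0("i", 1:n))
  fit <- pamCluster(m, 3)
  perm <- sample(n)
  fitP <- pamCluster(m[perm, perm], 3)
  # same partition up to relabeling
  expect_equal(fit@totalCost, fitP@totalCost, tolerance = 1e-12)
  a <- clusterAssignments(fit)[perm]
  b <- clusterAssignments(fitP)
  expect_equal(length(unique(paste(a, b))), 3L)
})

test_that("silhouette widths match the hand-computed two-pair example", {
  m <- abs(outer(c(0, 1, 10, 11), c(0, 1, 10, 11), "-"))
  sil <- silhouetteWidths(m, c(1, 1, 2, 2))
  expect_equal(sil$s, c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5),
               tolerance = 1e-4)
  expect_equal(sil$asw, 0.8997, tolerance = 1e-4)
})

test_that("silhouette handles degenerate ties and singletons by the zero convention", {
  m <- matrix(0, 4, 4)
  sil <- silhouetteWidths(m, c(1, 1, 2, 2))
  expect_equal(sil$s, rep(0, 4))
  m2 <- abs(outer(1:4, 1:4, "-")) / 3
  sil2 <- silhouetteWidths(m2, c(1, 2, 2, 2))
  expect_equal(sil2$s[1], 0)   # singleton cluster
})

test_that("silhouette matches a literal re-implementation and the cluster package", {
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    m <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    cl <- sample(1:3, n, replace = TRUE)
    if (length(unique(cl)) < 2) next
    sil <- silhouetteWidths(m, cl)
    expect_equal(sil$s, silhouetteOracle(m, cl), tolerance = 1e-12)
    if (requireNamespace("cluster", quietly = TRUE) &&
        all(tabulate(cl) > 0)) {
      ref <- cluster::silhouette(cl, dmatrix = m)
      if (!is.null(dim(ref)))
        expect_equal(sil$s, unname(ref[, "sil_width"]), tolerance = 1e-12)
    }
  }
})

test_that("selectK finds the true number of well-separated blobs", {
  for (seed in 1:5) {
    two <- selectK(gowerMatrix(blobTable(10, 2, seed = seed)))
    expect_equal(selectedK(two), 2L)
    expect_false(weakStructure(two))
    three <- selectK(gowerMatrix(blobTable(8, 3, seed = seed)))
    expect_equal(selectedK(three), 3L)
  }
})

test_that("near-uniform dissimilarities are flagged as weak structure (k = 1)", {
  set.seed(99)
  hits <- vapply(1:10, function(i) {
    n <- 20
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.4, 0.6)
    m <- m + t(m)
    dimnames(m) <- list(1:n, 1:n)
    ks <- selectK(m)
    weakStructure(ks) && selectedK(ks) == 1L
  }, TRUE)
  expect_true(all(hits))
})

test_that("ASW lies in [-1, 1] and grows towards 1 with blob separation", {
  asw <- vapply(c(2, 6, 20), function(sep) {
    ks <- selectK(gowerMatrix(blobTable(8, 2, sep = sep, seed = 4)))
    max(avgSilWidth(ks))
  }, 0)
  expect_true(all(asw >= -1 & asw <= 1))
  expect_true(all(diff(asw) >= 0))
  expect_gt(asw[3], 0.9)
})

test_that("cluster/region concordance is a matching-invariant agreement fraction", {
  cl <- c(1, 1, 2, 2, 3, 3)
  expect_equal(clusterRegionConcordance(cl, cl)$agreement, 1)
  # renaming regions does not change the agreement
  expect_equal(
    clusterRegionConcordance(cl, c("x", "x", "y", "y", "z", "z"))$agreement,
    1)
  expect_equal(
    clusterRegionConcordance(c(1, 2, 1, 2), c("a", "a", "b", "b"))$agreement,
    0.5)
  expect_error(clusterRegionConcordance(1:3, c("a", "a")), "length")
  expect_error(clusterRegionConcordance(1:3, rep("a", 3)), "2 regions")
})

test_that("concordance of a random balanced assignment is near half", {
  set.seed(5)
  ag <- replicate(200, {
    clusterRegionConcordance(sample(rep(1:2, 10)),
                             rep(c("e", "w"), 10))$agreement
  })
  expect_gt(mean(ag), 0.5)          # max-matching inflates above 0.5
  expect_lt(mean(ag), 0.65)
})

test_that("PAM agrees with the cluster package on clean partitions", {
  skip_if_not_installed("cluster")
  for (seed in 1:5) {
    tab <- blobTable(7, 3, seed = seed)
    m <- dissimMatrix(gowerMatrix(tab))
    fit <- pamCluster(m, 3)
    ref <- cluster::pam(as.dist(m), 3)
    expect_equal(fit@totalCost, sum(ref$clusinfo[, "av_diss"] *
                                      ref$clusinfo[, "size"]),
                 tolerance = 1e-8)
    expect_equal(length(unique(paste(clusterAssignments(fit),
                                     ref$clustering))), 3L)
  }
})
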