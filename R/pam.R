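## Partitioning around medoids on a precomputed dissimilarity matrix:
## classic BUILD followed by SWAP, accepting the single best cost-reducing
## (medoid, non-medoid) exchange per iteration until no exchange reduces
## the cost.  All ties break towards the lowest individual index so the
## result is fully deterministic and invariant under re-runs.

.checkDissim <- function(D) {
  m <- if (is(D, "SongDissimilarity")) dissimMatrix(D) else as.matrix(D)
  if (anyNA(m))
    stop("dissimilarity matrix has undefined entries; drop individuals ",
         "with no co-observed features before clustering")
  m
}

## Certified optimum by enumeration of all medoid sets (small problems).
## combn enumerates in lexicographic order, so keeping the first strict
## improvement yields the lexicographically smallest optimal set.
.pamExact <- function(m, k) {
  n <- nrow(m)
  sets <- utils::combn(n, k)
  bestCost <- Inf; best <- NULL
  for (s in seq_len(ncol(sets))) {
    med <- sets[, s]
    cost <- sum(do.call(pmin, lapply(med, function(j) m[, j])))
    if (cost < bestCost - 1e-12) { bestCost <- cost; best <- med }
  }
  fit <- .assignCost(m, best)
  sil <- if (k >= 2L) silhouetteWidths(m, fit$clustering) else
    list(s = numeric(0), asw = NA_real_)
  new("PamResult", k = k, medoids = as.integer(best),
      clustering = as.integer(fit$clustering), totalCost = fit$cost,
      silhouette = sil$s, avgSilWidth = sil$asw)
}

.assignCost <- function(m, medoids) {
  sub <- m[, medoids, drop = FALSE]
  nearest <- max.col(-sub, ties.method = "first")
  list(clustering = nearest,
       cost = sum(sub[cbind(seq_len(nrow(m)), nearest)]))
}

#' Cluster a dissimilarity matrix around k medoids
#'
#' @param D a \code{SongDissimilarity} or symmetric dissimilarity matrix
#'   with no undefined entries.
#' @param k number of clusters, \code{1 <= k < n}.  With \code{k = 1} the
#'   medoid is the individual minimising the row sum and the silhouette is
#'   undefined (empty slot, \code{avgSilWidth = NA}).
#' @param maxSwapIter cap on SWAP iterations (each accepts at most one
#'   exchange); the algorithm stops earlier as soon as no exchange reduces
#'   the total cost.
#' @param exactLimit when the number of candidate medoid sets
#'   \code{choose(n, k)} is at most this, the certified global optimum is
#'   found by exhaustive enumeration (ties resolved to the
#'   lexicographically smallest medoid set); above it, the swap heuristic
#'   is used.  Set to 0 to force the heuristic.
#' @details Swap-based k-medoids search is a local search: on a small
#'   fraction of instances it stops at a configuration no single exchange
#'   can improve that is still not globally optimal.  Because the matrices
#'   arising here are small enough for k = 2-3, enumeration is affordable
#'   exactly where the silhouette scan usually lands, so small problems
#'   are solved exactly by default.
#' @return A \code{\linkS4class{PamResult}}.
#' @examples
#' m <- abs(outer(c(0, 1, 10, 11), c(0, 1, 10, 11), "-")) / 11
#' dimnames(m) <- list(letters[1:4], letters[1:4])
#' pamCluster(m, k = 2)
#' @export
pamCluster <- function(D, k, maxSwapIter = 100L, exactLimit = 20000L) {
  m <- .checkDissim(D)
  n <- nrow(m)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop("k must satisfy 1 <= k < n (n = ", n, ", k = ", k, ")")

  if (choose(n, k) <= exactLimit)
    return(.pamExact(m, k))

  ## BUILD: start from the most central point, then greedily add the point
  ## giving the largest cost decrease; ties -> lowest index.
  medoids <- which.min(rowSums(m))
  d1 <- m[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gain <- vapply(cand, function(h) sum(pmax(d1 - m[, h], 0)), 0)
    medoids <- c(medoids, cand[which.max(gain)])
    d1 <- pmin(d1, m[, medoids[length(medoids)]])
  }
  medoids <- sort(medoids)

  ## SWAP: best single exchange per iteration, strict improvement only.
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxSwapIter) break
    sub <- m[, medoids, drop = FALSE]
    ord1 <- max.col(-sub, ties.method = "first")
    d1 <- sub[cbind(seq_len(n), ord1)]
    d2 <- if (k >= 2L) {
      masked <- sub
      masked[cbind(seq_len(n), ord1)] <- Inf
      masked[cbind(seq_len(n), max.col(-masked, ties.method = "first"))]
    } else rep(Inf, n)
    nearestMed <- medoids[ord1]
    best <- list(delta = -1e-12, m = NA_integer_, h = NA_integer_)
    nonMed <- setdiff(seq_len(n), medoids)
    for (mi in medoids) {
      isNear <- nearestMed == mi
      for (h in nonMed) {
        dh <- m[, h]
        delta <- sum(pmin(d2[isNear], dh[isNear]) - d1[isNear]) +
                 sum(pmin(dh[!isNear] - d1[!isNear], 0))
        if (delta < best$delta) best <- list(delta = delta, m = mi, h = h)
      }
    }
    if (is.na(best$m)) break
    medoids <- sort(c(setdiff(medoids, best$m), best$h))
  }

  fit <- .assignCost(m, medoids)
  sil <- if (k >= 2L) silhouetteWidths(m, fit$clustering) else
    list(s = numeric(0), asw = NA_real_)
  new("PamResult", k = k, medoids = as.integer(medoids),
      clustering = as.integer(fit$clustering), totalCost = fit$cost,
      silhouette = sil$s, avgSilWidth = sil$asw)
}

#' Silhouette widths of a clustering
#'
#' For each individual, \code{s(i) = (b(i) - a(i)) / max(a(i), b(i))} where
#' \code{a(i)} is the mean dissimilarity to its own cluster (excluding
#' itself) and \code{b(i)} the smallest mean dissimilarity to any other
#' cluster.  Members of singleton clusters score 0, as does the degenerate
#' tie \code{a = b = 0}.
#'
#' @param D dissimilarity matrix or \code{SongDissimilarity}.
#' @param clustering integer cluster assignment with at least 2 clusters.
#' @return List with per-individual widths \code{s} and their mean
#'   \code{asw}.
#' @export
silhouetteWidths <- function(D, clustering) {
  m <- .checkDissim(D)
  n <- nrow(m)
  cl <- as.integer(factor(clustering))
  ks <- max(cl)
  if (ks < 2L) stop("silhouette is undefined for a single cluster")
  sizes <- tabulate(cl, ks)
  ## mean dissimilarity from each point to each cluster
  member <- outer(cl, seq_len(ks), "==") * 1
  sums <- m %*% member                      # n x ks
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[own] == 1L) { s[i] <- 0; next }
    a <- sums[i, own] / (sizes[own] - 1L)
    b <- min(sums[i, -own] / sizes[-own])
    s[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  list(s = s, asw = mean(s))
}

#' Select the number of clusters by average silhouette width
#'
#' Runs \code{\link{pamCluster}} for each k in the scanned range (default
#' 2-8, truncated below n) and picks the k with the highest average
#' silhouette width.  When even the best ASW falls below
#' \code{weakAswThreshold}, the profile is judged to show no real cluster
#' structure and k = 1 is reported with \code{weakStructure = TRUE}.
#'
#' @param D dissimilarity matrix or \code{SongDissimilarity}.
#' @param kMin,kMax scanned k range (defaults 2 and 8).
#' @param weakAswThreshold ASW below which structure is called weak
#'   (default 0.25).
#' @return A \code{\linkS4class{KSelection}}.
#' @export
selectK <- function(D, kMin = 2L, kMax = 8L, weakAswThreshold = 0.25) {
  m <- .checkDissim(D)
  n <- nrow(m)
  kMax <- min(as.integer(kMax), n - 1L)
  kMin <- as.integer(kMin)
  if (kMin > kMax) stop("need n > kMin individuals to scan k")
  ks <- kMin:kMax
  fits <- lapply(ks, function(k) pamCluster(m, k))
  names(fits) <- ks
  asw <- vapply(fits, avgSilWidth, 0)
  names(asw) <- ks
  bestIdx <- which.max(asw)                 # ties -> smallest k
  weak <- asw[bestIdx] < weakAswThreshold
  new("KSelection", aswByK = asw,
      selectedK = if (weak) 1L else ks[bestIdx],
      weakStructure = weak, threshold = weakAswThreshold, fits = fits)
}

#' Agreement between a clustering and a regional labelling
#'
#' Quantifies whether blindly determined clusters can be distinguished by
#' geography: builds the cluster-by-region contingency table and returns
#' the largest fraction of individuals correctly co-labelled under any
#' one-to-one matching of clusters to regions.  Invariant under renaming
#' of either labelling.
#'
#' @param clustering integer or factor cluster assignment.
#' @param regions region labels of the same length, at least 2 distinct.
#' @return List with \code{agreement} in (0, 1] and the contingency
#'   \code{table}.
#' @export
clusterRegionConcordance <- function(clustering, regions) {
  if (length(clustering) != length(regions))
    stop("clustering and regions must have the same length")
  if (length(unique(regions)) < 2L) stop("need at least 2 regions")
  tab <- table(cluster = clustering, region = regions)
  r <- nrow(tab); c <- ncol(tab)
  ## max-weight injective matching of the smaller side into the larger
  small <- min(r, c)
  M <- if (r <= c) tab else t(tab)
  ## counts are non-negative, so matching every row of the smaller side
  ## is always optimal; enumerate injective assignments
  bestMatch <- function(rows, freeCols) {
    if (length(rows) == 0L) return(0)
    i <- rows[1L]
    best <- 0
    for (jj in seq_along(freeCols)) {
      best <- max(best, M[i, freeCols[jj]] +
                    bestMatch(rows[-1L], freeCols[-jj]))
    }
    best
  }
  hit <- bestMatch(seq_len(small), seq_len(ncol(M)))
  list(agreement = as.numeric(hit / length(clustering)), table = tab)
}

## ---- accessors & show -----------------------------------------------------

#' Accessors for PamResult
#'
#' \code{clusterAssignments} returns the per-individual cluster labels,
#' \code{medoids} the medoid indices, \code{avgSilWidth} the average
#' silhouette width.
#' @param x a \code{PamResult} (or \code{KSelection} for
#'   \code{avgSilWidth} of the selected fit).
#' @name PamResult-accessors
#' @aliases clusterAssignments medoids avgSilWidth
NULL

#' @rdname PamResult-accessors
#' @export
setMethod("clusterAssignments", "PamResult", function(x) x@clustering)

#' @rdname PamResult-accessors
#' @export
setMethod("medoids", "PamResult", function(x) x@medoids)

#' @rdname PamResult-accessors
#' @export
setMethod("avgSilWidth", "PamResult", function(x) x@avgSilWidth)

setMethod("show", "PamResult", function(object) {
  cat("PamResult: k =", object@k,
      sprintf("| total cost %.4f", object@totalCost),
      if (object@k >= 2L) sprintf("| ASW %.3f", object@avgSilWidth) else "",
      "\n")
  cat("  cluster sizes:", paste(tabulate(object@clustering, object@k),
                                collapse = ", "), "\n")
})

#' Accessors for KSelection
#'
#' \code{selectedK} returns the chosen number of clusters (1 when the
#' structure is weak); \code{weakStructure} the weak-structure flag;
#' \code{avgSilWidth} the ASW profile over the scanned k.
#' @param x a \code{KSelection}.
#' @name KSelection-accessors
#' @aliases selectedK weakStructure
NULL

#' @rdname KSelection-accessors
#' @export
setMethod("selectedK", "KSelection", function(x) x@selectedK)

#' @rdname KSelection-accessors
#' @export
setMethod("weakStructure", "KSelection", function(x) x@weakStructure)

#' @rdname KSelection-accessors
#' @export
setMethod("avgSilWidth", "KSelection", function(x) x@aswByK)

#' Retrieve the PAM fit at the selected (or any scanned) k
#' @param x a \code{KSelection}.
#' @param k which k (default: the selected k; the best scanned k when the
#'   selection fell back to 1).
#' @return A \code{PamResult}.
#' @export
selectedFit <- function(x, k = NULL) {
  stopifnot(is(x, "KSelection"))
  if (is.null(k))
    k <- if (x@selectedK >= 2L) x@selectedK else
      as.integer(names(which.max(x@aswByK)))
  x@fits[[as.character(k)]]
}

setMethod("show", "KSelection", function(object) {
  cat("KSelection: k =", object@selectedK,
      if (object@weakStructure)
        sprintf("(weak structure: max ASW %.3f < %.2f)",
                max(object@aswByK), object@threshold) else "", "\n")
  cat("  ASW by k:", paste(sprintf("%s:%.3f", names(object@aswByK),
                                   object@aswByK), collapse = "  "), "\n")
})
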