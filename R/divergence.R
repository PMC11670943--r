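## Inferential core: three-category within/between permutation test on a
## dissimilarity matrix, p-value adjustment, the joint-CDF divergence
## score Delta-p with per-feature Hedge's g, the two-sample t-test, and
## rank correlation of divergence scores against relative mtDNA
## divergence times.

#' Partition pairwise dissimilarities into within/between categories
#'
#' Splits the strict upper triangle of a dissimilarity matrix into the
#' three comparison categories of a two-taxon design: pairs within the
#' first taxon, pairs within the second, and pairs spanning both.  The
#' partition is exhaustive and disjoint with sizes
#' nA(nA-1)/2, nB(nB-1)/2 and nA*nB.
#'
#' @param D a \code{SongDissimilarity} or dissimilarity matrix.
#' @param labels binary taxon labels, one per individual; the first label
#'   in order of appearance is taken as taxon A (conventionally the
#'   eastern taxon).
#' @return List with the three value vectors (named
#'   \code{within_<A>}, \code{within_<B>}, \code{between}), the matching
#'   index-pair matrices in \code{pairs}, and \code{taxa}.
#' @export
categorizeDissimilarities <- function(D, labels) {
  m <- .checkDissim(D)
  labels <- as.character(labels)
  taxa <- unique(labels)
  if (length(taxa) != 2L)
    stop("labels must be binary (got ", length(taxa), " distinct labels)")
  if (length(labels) != nrow(m))
    stop("one label per individual is required")
  if (min(table(labels)) < 2L)
    stop("need at least 2 individuals per taxon")
  idx <- which(upper.tri(m), arr.ind = TRUE)
  li <- labels[idx[, 1L]]; lj <- labels[idx[, 2L]]
  cat3 <- ifelse(li != lj, "between",
                 ifelse(li == taxa[1L], paste0("within_", taxa[1L]),
                        paste0("within_", taxa[2L])))
  vals <- m[idx]
  out <- split(vals, cat3)[c(paste0("within_", taxa), "between")]
  pairs <- split.data.frame(idx, cat3)[c(paste0("within_", taxa), "between")]
  list(values = out, pairs = pairs, taxa = taxa)
}

.categoryMeans <- function(m, e) {
  ## e: 0/1 indicator of taxon A; returns means of the three categories
  nA <- sum(e); nB <- length(e) - nA
  Me <- m %*% e
  sAA <- sum(e * Me)                         # 2 * sum within A
  sAB <- sum((1 - e) * Me)
  sTot <- sum(m)
  sBB <- sTot - 2 * sum(Me) + sAA
  c(withinA = sAA / (nA * (nA - 1)),
    withinB = sBB / (nB * (nB - 1)),
    between = sAB / (nA * nB))
}

#' Monte Carlo permutation test on dissimilarity categories
#'
#' Tests whether the mean dissimilarity in one category exceeds (or
#' differs from) that in another, using the statistic
#' mean(category A) - mean(category B).  The null distribution is built
#' by permuting taxon labels at the individual level (group sizes fixed)
#' and re-deriving the categories from the unchanged dissimilarity matrix
#' each replicate; the p-value follows the add-one rule (b + 1)/(B + 1).
#'
#' @param D a \code{SongDissimilarity} or dissimilarity matrix.
#' @param labels binary taxon labels per individual.
#' @param comparison length-2 character: the two categories compared, each
#'   \code{"between"} or \code{"within_<label>"}; e.g.
#'   \code{c("between", "within_east")}.
#' @param B number of Monte Carlo replicates (default 10000).
#' @param alternative \code{"greater"} (is A's mean larger?) or
#'   \code{"two.sided"}.
#' @param seed integer seed making the permutation stream reproducible.
#' @return A \code{\linkS4class{PermutationResult}}.
#' @export
permutationTest <- function(D, labels, comparison, B = 10000L,
                            alternative = c("greater", "two.sided"),
                            seed = 1L) {
  alternative <- match.arg(alternative)
  m <- .checkDissim(D)
  labels <- as.character(labels)
  taxa <- unique(labels)
  if (length(taxa) != 2L) stop("labels must be binary")
  if (B < 99L) stop("B must be at least 99")
  catNames <- c(withinA = paste0("within_", taxa[1L]),
                withinB = paste0("within_", taxa[2L]),
                between = "between")
  comparison <- as.character(comparison)
  sel <- match(comparison, catNames)
  if (length(sel) != 2L || anyNA(sel))
    stop("comparison must name two of: ",
         paste(catNames, collapse = ", "))
  if (min(table(labels)) < 2L)
    stop("a category is empty under the observed labels")
  e <- as.numeric(labels == taxa[1L])
  n <- length(e); nA <- sum(e)
  obs <- .categoryMeans(m, e)
  observed <- unname(obs[sel[1L]] - obs[sel[2L]])
  B <- as.integer(B)
  P <- .withSeed(seed, {
    vapply(seq_len(B), function(b) {
      eb <- numeric(n); eb[sample.int(n, nA)] <- 1; eb
    }, numeric(n))
  })
  MP <- m %*% P
  colMe <- colSums(MP)
  sAA <- colSums(P * MP)
  sAB <- colSums((1 - P) * MP)
  sBB <- sum(m) - 2 * colMe + sAA
  nB <- n - nA
  means <- rbind(withinA = sAA / (nA * (nA - 1)),
                 withinB = sBB / (nB * (nB - 1)),
                 between = sAB / (nA * nB))
  null <- means[sel[1L], ] - means[sel[2L], ]
  eps <- 1e-12
  b <- if (alternative == "greater") sum(null >= observed - eps)
       else sum(abs(null) >= abs(observed) - eps)
  new("PermutationResult",
      comparison = paste(comparison, collapse = "_vs_"),
      observed = observed, B = B, pRaw = (b + 1) / (B + 1),
      alternative = alternative, seed = as.integer(seed))
}

#' @rdname PermutationResult-accessors
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pRaw)

#' Accessors for PermutationResult
#'
#' \code{pValue} returns the raw Monte Carlo p-value.
#' @param x a \code{PermutationResult}.
#' @name PermutationResult-accessors
#' @aliases pValue
NULL

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult [%s, %s]: observed %.4f, p = %.4g (B = %d)\n",
    object@comparison, object@alternative, object@observed, object@pRaw,
    object@B))
})

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up false discovery rate or Bonferroni
#' adjustment (p * m capped at 1), optionally against a family larger
#' than the list itself.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method \code{"benjamini_hochberg"} or \code{"bonferroni"}.
#' @param familySize the family size m (default \code{length(p)}); the
#'   Bonferroni family of a batch of pair analyses is 3 comparisons per
#'   analysis.
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
adjustPValues <- function(p, method = c("benjamini_hochberg", "bonferroni"),
                          familySize = length(p)) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value list")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = switch(method,
                                     benjamini_hochberg = "BH",
                                     bonferroni = "bonferroni"),
                  n = max(familySize, length(p)))
}

#' Per-test Bonferroni criterion
#'
#' The per-test significance criterion for a family of
#' \code{comparisons * analyses} tests at familywise level \code{alpha};
#' e.g. 3 within/between comparisons over 9 pair analyses at
#' \code{alpha = 0.05} gives 0.05/27 = 0.00185 (3 s.f.).
#'
#' @param alpha familywise error rate.
#' @param comparisons comparisons per analysis (default 3).
#' @param analyses number of analyses in the batch.
#' @return The per-test criterion \code{alpha / (comparisons * analyses)}.
#' @export
bonferroniCriterion <- function(alpha = 0.05, comparisons = 3L,
                                analyses = 1L) {
  alpha / (comparisons * analyses)
}

#' Joint empirical CDF percentile
#'
#' Right-continuous empirical CDF of the pooled values, on a 0-100 scale:
#' \code{100 * #(v <= x) / N}.
#'
#' @param pool non-empty numeric vector of pooled values.
#' @param x points at which to evaluate (vectorised).
#' @return Percentiles in [0, 100].
#' @export
jointEcdfPercentile <- function(pool, x) {
  pool <- pool[!is.na(pool)]
  if (length(pool) == 0L) stop("empty pool")
  if (any(!is.finite(x))) stop("x must be finite")
  100 * vapply(x, function(xi) mean(pool <= xi), 0)
}

#' Hedge's g standardised mean difference
#'
#' Bias-corrected standardised mean difference
#' \code{g = J * (mean(xA) - mean(xB)) / s_pooled} with the small-sample
#' correction \code{J = 1 - 3 / (4 (nA + nB) - 9)} and the
#' (n-1)-weighted pooled standard deviation.
#'
#' @param xA,xB numeric samples with at least 2 observed values each.
#' @return Hedge's g (antisymmetric in A and B).
#' @export
hedgesG <- function(xA, xB) {
  xA <- xA[!is.na(xA)]; xB <- xB[!is.na(xB)]
  nA <- length(xA); nB <- length(xB)
  if (nA < 2L || nB < 2L) stop("need at least 2 observed values per sample")
  sp2 <- ((nA - 1) * stats::var(xA) + (nB - 1) * stats::var(xB)) /
    (nA + nB - 2)
  if (sp2 == 0) stop("zero pooled variance")
  J <- 1 - 3 / (4 * (nA + nB) - 9)
  J * (mean(xA) - mean(xB)) / sqrt(sp2)
}

#' Joint-CDF phenotypic divergence score Delta-p
#'
#' For each usable feature the two populations' observed values are
#' pooled and a joint empirical CDF formed; each population's coordinate
#' on that feature is the percentile (0-100) of its median under the
#' pooled CDF.  Delta-p is the Euclidean distance between the two
#' populations' coordinate vectors across all usable features, so it is
#' non-negative, symmetric, bounded by 100 * sqrt(#features), and
#' invariant under any strictly increasing per-feature transform applied
#' to both populations.  Per-feature Hedge's g is reported alongside.
#'
#' Features must be observed in at least one individual of each
#' population to be used; others are dropped with a message.  Categorical
#' (slur) features are excluded by default because the CDF construction
#' presumes orderable values; \code{includeCategorical = TRUE} encodes
#' them 0/1 (U = 0, D = 1) instead.
#'
#' @param tableA,tableB \code{SongFeatureTable}s for the two populations
#'   (at least 2 individuals each) sharing measurement codes.
#' @param features optional subset of codes to consider.
#' @param includeCategorical include slur features via 0/1 encoding.
#' @return A \code{\linkS4class{DeltaPResult}}.
#' @export
deltaP <- function(tableA, tableB, features = NULL,
                   includeCategorical = FALSE) {
  if (nrow(featureValues(tableA)) < 2L || nrow(featureValues(tableB)) < 2L)
    stop("need at least 2 individuals per population")
  shared <- intersect(featureCodes(tableA), featureCodes(tableB))
  if (!is.null(features)) shared <- intersect(shared, features)
  if (length(shared) == 0L) stop("no shared features")
  dA <- descriptors(tableA)
  dropped <- character()
  coords <- matrix(NA_real_, 2L, 0L)
  gs <- numeric(0)
  used <- character(0)
  for (code in shared) {
    dtype <- dA$dtype[match(code, dA$code)]
    a <- featureValues(tableA)[[code]]
    b <- featureValues(tableB)[[code]]
    if (dtype == "categorical") {
      if (!includeCategorical) { dropped <- c(dropped, code); next }
      a <- as.numeric(a == "D"); b <- as.numeric(b == "D")
    }
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) {
      dropped <- c(dropped, code); next
    }
    pool <- c(a, b)
    cA <- jointEcdfPercentile(pool, stats::median(a))
    cB <- jointEcdfPercentile(pool, stats::median(b))
    coords <- cbind(coords, c(cA, cB))
    g <- if (length(a) >= 2L && length(b) >= 2L &&
             (stats::var(a) > 0 || stats::var(b) > 0))
      hedgesG(a, b) else NA_real_
    gs <- c(gs, g)
    used <- c(used, code)
  }
  if (length(used) == 0L) stop("no usable features for Delta-p")
  if (length(dropped))
    message("Delta-p: dropped features ", paste(dropped, collapse = ", "))
  dimnames(coords) <- list(c("A", "B"), used)
  names(gs) <- used
  new("DeltaPResult",
      deltaP = sqrt(sum((coords[1L, ] - coords[2L, ])^2)),
      coordinates = coords, hedgesG = gs,
      featuresUsed = used, featuresDropped = dropped)
}

#' @rdname DeltaPResult-accessors
#' @export
setMethod("deltaPScore", "DeltaPResult", function(x) x@deltaP)

#' Accessors for DeltaPResult
#'
#' \code{deltaPScore} returns the scalar divergence score.
#' @param x a \code{DeltaPResult}.
#' @name DeltaPResult-accessors
#' @aliases deltaPScore
NULL

setMethod("show", "DeltaPResult", function(object) {
  cat(sprintf("DeltaPResult: Delta-p = %.2f over %d features",
              object@deltaP, length(object@featuresUsed)))
  if (length(object@featuresDropped))
    cat(sprintf(" (%d dropped)", length(object@featuresDropped)))
  cat("\n")
})

#' Two-sample t-test
#'
#' Pooled-variance (df = nA + nB - 2) or Welch-Satterthwaite two-sample
#' t-test, two-sided.
#'
#' @param xA,xB numeric samples with at least 2 observed values each.
#' @param variant \code{"pooled"} or \code{"welch"}.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
twoSampleT <- function(xA, xB, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  xA <- xA[!is.na(xA)]; xB <- xB[!is.na(xB)]
  if (length(xA) < 2L || length(xB) < 2L)
    stop("need at least 2 observed values per sample")
  if (stats::var(xA) == 0 && stats::var(xB) == 0) {
    if (mean(xA) == mean(xB)) return(list(t = 0, df = length(xA) +
                                            length(xB) - 2, p = 1))
    stop("zero variance in both samples")
  }
  fit <- stats::t.test(xA, xB, var.equal = variant == "pooled")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties; the p-value uses exact
#' enumeration for n <= 9 without ties and the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with \code{rho} and \code{p}.
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors of length >= 3")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("rank correlation undefined for a constant vector")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  fit <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 9L && !ties))
  list(rho = unname(fit$estimate), p = fit$p.value)
}

#' Read a divergence table
#'
#' CSV with columns \code{pair_id}, \code{delta_p} (non-negative score)
#' and \code{mtdna_relative_time} (finite, non-negative relative time).
#'
#' @param path CSV path.
#' @return Validated data.frame, one row per pair.
#' @export
readDivergenceTable <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("pair_id", "delta_p", "mtdna_relative_time")
  if (!all(need %in% colnames(d)))
    stop("divergence table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(d$pair_id)) stop("one row per pair is required")
  if (any(!is.finite(d$delta_p)) || any(d$delta_p < 0))
    stop("delta_p must be finite and >= 0")
  if (any(!is.finite(d$mtdna_relative_time)) ||
      any(d$mtdna_relative_time < 0))
    stop("relative times must be finite and >= 0")
  d
}

#' Correlate song divergence with mtDNA divergence time
#'
#' Spearman rank correlation of the Delta-p divergence scores against the
#' relative mtDNA divergence times of a divergence table.
#'
#' @param divergence data.frame as from \code{\link{readDivergenceTable}}
#'   or \code{\link{generateDivergenceTable}}.
#' @return List with \code{rho} and \code{p}.
#' @export
correlateDivergence <- function(divergence) {
  spearmanCorrelation(divergence$delta_p, divergence$mtdna_relative_time)
}
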