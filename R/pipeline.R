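## Orchestration of the two analysis scales: the between-taxa pair
## analysis (Gower -> PAM/silhouette -> mixed PCA -> three permutation
## comparisons -> Delta-p -> cluster/taxon concordance) and the
## within-taxon variant screen.

## Columns a PCA cannot digest (all-missing, constant numeric,
## single-level categorical) are dropped up front, with a message.
.pcaReady <- function(x) {
  rep <- validateFeatureTable(x)
  drop <- rep$code[rep$all_missing | rep$constant]
  if (length(drop)) {
    message("PCA: dropping unusable columns ", paste(drop, collapse = ", "))
    x <- x[, setdiff(featureCodes(x), drop)]
  }
  x
}

#' Run a full between-taxa pair analysis
#'
#' Reconciles the two tables' feature sets by code intersection, pools
#' them, and executes the whole between-taxa pipeline: Gower
#' dissimilarity, silhouette-guided PAM clustering (k scanned 2-8),
#' mixed PCA, the three within/between Monte Carlo permutation
#' comparisons with BH and Bonferroni adjustment, the Delta-p divergence
#' score, and the cluster-vs-taxon concordance.  Everything downstream
#' of the seed is deterministic, so re-running with the same inputs and
#' seed reproduces the report exactly.
#'
#' @param east,west \code{SongFeatureTable}s of the two taxa.
#' @param B Monte Carlo replicates per permutation comparison.
#' @param seed integer seed stamped into the report.
#' @param kMin,kMax scanned cluster-number range.
#' @param weakAswThreshold average-silhouette threshold below which
#'   cluster structure is reported as absent (k = 1).
#' @param nComponents leading components reported from the PCA.
#' @param familyAnalyses number of pair analyses in the batch this run
#'   belongs to; the Bonferroni family size is 3 * familyAnalyses.
#' @param includeCategorical passed to \code{\link{deltaP}}.
#' @return A \code{\linkS4class{PairReport}}.
#' @export
runPairAnalysis <- function(east, west, B = 10000L, seed = 1L,
                            kMin = 2L, kMax = 8L, weakAswThreshold = 0.25,
                            nComponents = 6L, familyAnalyses = 1L,
                            includeCategorical = FALSE) {
  pooled <- poolFeatureTables(east, west)
  shared <- featureCodes(pooled)
  labels <- taxonLabels(pooled)
  taxa <- unique(labels)

  gow <- gowerMatrix(pooled)
  m <- dissimMatrix(gow)
  up <- m[upper.tri(m)]
  gowerSummary <- list(mean = mean(up, na.rm = TRUE),
                       max = max(up, na.rm = TRUE),
                       nUndefined = sum(is.na(up)))

  ksel <- selectK(gow, kMin = kMin, kMax = kMax,
                  weakAswThreshold = weakAswThreshold)
  fit <- selectedFit(ksel)

  pca <- mixedPCA(.pcaReady(pooled), nComponents = nComponents)
  pcaSummary <- list(
    pctVariance = pctVariance(pca)[seq_len(min(nComponents,
                                               length(pctVariance(pca))))],
    topPC1 = topLoadingFeature(pca, 1L),
    topPC2 = if (length(eigenvalues(pca)) >= 2L)
      topLoadingFeature(pca, 2L) else NULL)

  streams <- .substreams(seed, c("perm1", "perm2", "perm3"))
  comparisons <- list(
    c("between", paste0("within_", taxa[1L])),
    c("between", paste0("within_", taxa[2L])),
    c(paste0("within_", taxa[1L]), paste0("within_", taxa[2L])))
  sides <- c("greater", "greater", "two.sided")
  perms <- lapply(1:3, function(i)
    permutationTest(gow, labels, comparisons[[i]], B = B,
                    alternative = sides[i], seed = streams[[i]]))
  pRaw <- vapply(perms, pValue, 0)
  familySize <- 3L * as.integer(familyAnalyses)
  permutation <- list(
    tests = perms,
    pRaw = pRaw,
    pFdr = adjustPValues(pRaw, "benjamini_hochberg"),
    pBonferroni = adjustPValues(pRaw, "bonferroni",
                                familySize = familySize),
    bonferroniFamilySize = familySize,
    bonferroniCriterion = bonferroniCriterion(0.05, 3L, familyAnalyses))

  dp <- deltaP(east[, intersect(featureCodes(east), shared)],
               west[, intersect(featureCodes(west), shared)],
               includeCategorical = includeCategorical)

  conc <- clusterRegionConcordance(clusterAssignments(fit), labels)

  new("PairReport",
      inputs = list(n = as.list(table(labels)), features = shared,
                    droppedCodes = attr(pooled, "droppedCodes")),
      gowerSummary = gowerSummary,
      kSelection = ksel, clustering = fit,
      pca = pcaSummary, permutation = permutation, deltaP = dp,
      concordance = conc$agreement, seed = as.integer(seed))
}

#' Run a within-taxon variant screen
#'
#' Screens one taxon's table for a localised song variant: clusters the
#' table (Gower + PAM with silhouette-guided k), fits the mixed PCA and
#' takes the highest-loading feature of PC1, t-tests that feature
#' between the two largest clusters, and scores the concordance of the
#' clustering against a regional labelling.  A variant is called only
#' when (1) the clustering is non-weak (k >= 2) and (2) the
#' cluster/region concordance exceeds \code{concordanceThreshold}.
#'
#' @param x a \code{SongFeatureTable} of one taxon.
#' @param regions optional region labels per individual; alternatively
#'   \code{regionBox} (\code{c(latMin, latMax, lonMin, lonMax)}) derives
#'   inside/outside labels from the locality metadata.  When neither is
#'   given the concordance is not evaluated and no variant can be
#'   called.
#' @param regionBox optional bounding box, see \code{regions}.
#' @param kMin,kMax,weakAswThreshold clustering controls as in
#'   \code{\link{runPairAnalysis}}.
#' @param concordanceThreshold minimum cluster/region agreement for a
#'   variant call (default 0.8).
#' @param tTestVariant \code{"pooled"} or \code{"welch"}.
#' @param seed integer seed stamped into the report.
#' @return A \code{\linkS4class{WithinReport}}.
#' @export
runWithinTaxonAnalysis <- function(x, regions = NULL, regionBox = NULL,
                                   kMin = 2L, kMax = 8L,
                                   weakAswThreshold = 0.25,
                                   concordanceThreshold = 0.8,
                                   tTestVariant = "pooled", seed = 1L) {
  if (nrow(featureValues(x)) < 2L * kMin)
    stop("need at least ", 2L * kMin, " individuals")
  s <- sampleData(x)
  if (is.null(regions) && !is.null(regionBox)) {
    if (all(is.na(s$latitude)) || all(is.na(s$longitude)))
      stop("regionBox concordance requires latitude/longitude metadata")
    regions <- ifelse(!is.na(s$latitude) & !is.na(s$longitude) &
                        s$latitude >= regionBox[1L] &
                        s$latitude <= regionBox[2L] &
                        s$longitude >= regionBox[3L] &
                        s$longitude <= regionBox[4L],
                      "inside", "outside")
  }

  gow <- gowerMatrix(x)
  ksel <- selectK(gow, kMin = kMin, kMax = kMax,
                  weakAswThreshold = weakAswThreshold)
  fit <- selectedFit(ksel)

  pca <- mixedPCA(.pcaReady(x))
  top <- topLoadingFeature(pca, 1L)

  clustered <- selectedK(ksel) >= 2L && !weakStructure(ksel)
  tt <- NULL
  if (clustered) {
    cl <- clusterAssignments(fit)
    big2 <- order(tabulate(cl), decreasing = TRUE)[1:2]
    colv <- featureValues(x)[[top$code]]
    if (is.numeric(colv)) {
      a <- colv[cl == big2[1L]]; b <- colv[cl == big2[2L]]
      if (sum(!is.na(a)) >= 2L && sum(!is.na(b)) >= 2L)
        tt <- twoSampleT(a, b, variant = tTestVariant)
    }
  }

  conc <- NA_real_
  if (!is.null(regions) && length(unique(regions)) >= 2L)
    conc <- clusterRegionConcordance(clusterAssignments(fit),
                                     regions)$agreement

  call <- isTRUE(clustered && !is.na(conc) && conc >= concordanceThreshold)
  new("WithinReport",
      kSelection = ksel,
      pca = list(pctVariance = pctVariance(pca)[
        seq_len(min(6L, length(pctVariance(pca))))]),
      topFeature = top$code,
      tTest = if (is.null(tt)) list() else tt,
      concordance = conc, variantCall = call, seed = as.integer(seed))
}

#' @rdname WithinReport-accessors
#' @export
setMethod("variantCall", "WithinReport", function(x) x@variantCall)

#' Accessors for WithinReport
#'
#' \code{variantCall} returns the boolean variant call.
#' @param x a \code{WithinReport}.
#' @name WithinReport-accessors
#' @aliases variantCall
NULL

setMethod("show", "PairReport", function(object) {
  n <- object@inputs$n
  cat("PairReport:", paste(sprintf("%s n=%d", names(n), unlist(n)),
                           collapse = ", "),
      "|", length(object@inputs$features), "shared features\n")
  cat(sprintf("  k = %d (ASW %.3f) | concordance %.3f\n",
              selectedK(object@kSelection),
              max(object@kSelection@aswByK), object@concordance))
  pv <- object@pca$pctVariance
  cat(sprintf("  PCA: PC1 %.2f%%, PC2 %.2f%%\n", pv[1L],
              if (length(pv) >= 2L) pv[2L] else NA))
  cat(sprintf("  Delta-p = %.2f | permutation p (raw): %s\n",
              deltaPScore(object@deltaP),
              paste(signif(object@permutation$pRaw, 3), collapse = ", ")))
})

setMethod("show", "WithinReport", function(object) {
  cat("WithinReport: k =", selectedK(object@kSelection),
      "| top PC1 feature", object@topFeature, "\n")
  cat(sprintf("  concordance %s | variant call: %s\n",
              ifelse(is.na(object@concordance), "not evaluated",
                     sprintf("%.3f", object@concordance)),
              object@variantCall))
})

## ---- report serialisation -------------------------------------------------

.kselToList <- function(k) list(aswByK = as.list(k@aswByK),
                                selectedK = k@selectedK,
                                weakStructure = k@weakStructure,
                                threshold = k@threshold)

#' Convert a report to a plain list
#'
#' Flattens a \code{PairReport} or \code{WithinReport} into nested lists
#' of base types ready for JSON serialisation.
#'
#' @param report a \code{PairReport} or \code{WithinReport}.
#' @return A named list.
#' @export
reportToList <- function(report) {
  if (is(report, "PairReport")) {
    perms <- lapply(report@permutation$tests, function(p)
      list(comparison = p@comparison, observed = p@observed, B = p@B,
           pRaw = p@pRaw, alternative = p@alternative, seed = p@seed))
    list(kind = "pair",
         inputs = report@inputs,
         gower = report@gowerSummary,
         kSelection = .kselToList(report@kSelection),
         clusterSizes = as.list(tabulate(
           clusterAssignments(report@clustering))),
         pca = list(pctVariance = as.list(report@pca$pctVariance),
                    topPC1 = report@pca$topPC1,
                    topPC2 = report@pca$topPC2),
         permutation = list(tests = perms,
                            pRaw = report@permutation$pRaw,
                            pFdr = report@permutation$pFdr,
                            pBonferroni = report@permutation$pBonferroni,
                            bonferroniFamilySize =
                              report@permutation$bonferroniFamilySize,
                            bonferroniCriterion =
                              report@permutation$bonferroniCriterion),
         deltaP = list(score = deltaPScore(report@deltaP),
                       featuresUsed = report@deltaP@featuresUsed,
                       featuresDropped = report@deltaP@featuresDropped,
                       hedgesG = as.list(report@deltaP@hedgesG)),
         concordance = report@concordance,
         seed = report@seed)
  } else if (is(report, "WithinReport")) {
    list(kind = "within",
         kSelection = .kselToList(report@kSelection),
         pca = report@pca,
         topFeature = report@topFeature,
         tTest = report@tTest,
         concordance = report@concordance,
         variantCall = report@variantCall,
         seed = report@seed)
  } else stop("unsupported report class")
}

#' Write a report to JSON
#'
#' @param report a \code{PairReport} or \code{WithinReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(reportToList(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' One-row flat summary of a pair analysis
#'
#' Mirrors the layout of a between-taxa results table: % variance of the
#' first two PCA components, % variance of the first two classical-MDS
#' axes of the Gower matrix (the ordination underlying cluster plots),
#' the selected k, and Delta-p.
#'
#' @param report a \code{PairReport}.
#' @param D optional \code{SongDissimilarity} of the pooled pair table;
#'   when supplied the MDS axis percentages are computed from it,
#'   otherwise they are \code{NA}.
#' @return One-row data.frame with columns \code{PC1_pct},
#'   \code{PC2_pct}, \code{Dim1_pct}, \code{Dim2_pct}, \code{k},
#'   \code{delta_p}.
#' @export
pairSummaryRow <- function(report, D = NULL) {
  dims <- c(NA_real_, NA_real_)
  if (!is.null(D)) {
    eig <- stats::cmdscale(dissimMatrix(D), k = 2L, eig = TRUE)$eig
    pos <- pmax(eig, 0)
    dims <- 100 * pos[1:2] / sum(pos)
  }
  pv <- report@pca$pctVariance
  data.frame(PC1_pct = pv[1L],
             PC2_pct = if (length(pv) >= 2L) pv[2L] else NA_real_,
             Dim1_pct = dims[1L], Dim2_pct = dims[2L],
             k = selectedK(report@kSelection),
             delta_p = deltaPScore(report@deltaP))
}
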