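#' @import methods
NULL

#' SongFeatureTable: individuals by mixed-type song features
#'
#' The central data container: one row per recorded individual, one column
#' per acoustic measurement (keyed by a measurement code, see
#' \code{\link{parseMeasurementCode}}), plus per-individual metadata.  Cells
#' are numeric or categorical; missing cells (e.g. because a song lacks a
#' syllable and so lacks every measurement of it) are \code{NA}, never zero.
#'
#' @slot values data.frame of measurements, rows = individuals (rownames are
#'   record ids), columns = measurement codes.  Numeric columns are double,
#'   categorical (slur) columns are character with levels \code{"U"}/\code{"D"}.
#' @slot descriptors data.frame of parsed code descriptors, one row per
#'   column of \code{values}, as returned by \code{parseMeasurementCode}.
#' @slot sampleData data.frame of per-individual metadata with the same
#'   rownames as \code{values}; recognised columns: \code{taxon},
#'   \code{latitude}, \code{longitude}, \code{sex}.
#' @export
setClass("SongFeatureTable",
  slots = c(values = "data.frame",
            descriptors = "data.frame",
            sampleData = "data.frame"))

setValidity("SongFeatureTable", function(object) {
  v <- object@values; d <- object@descriptors; s <- object@sampleData
  msgs <- character()
  if (ncol(v) != nrow(d))
    msgs <- c(msgs, "one descriptor row is required per value column")
  if (!identical(colnames(v), d$code))
    msgs <- c(msgs, "value column names must equal descriptor codes, in order")
  if (!identical(rownames(v), rownames(s)))
    msgs <- c(msgs, "values and sampleData must share rownames (record ids)")
  if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, "duplicate record ids")
  if (anyDuplicated(d$code))
    msgs <- c(msgs, "duplicate measurement codes")
  if (!"taxon" %in% colnames(s))
    msgs <- c(msgs, "sampleData must contain a 'taxon' column")
  if (length(msgs)) return(msgs)
  for (j in seq_len(ncol(v))) {
    x <- v[[j]]
    if (d$dtype[j] == "numeric") {
      if (!is.numeric(x))
        msgs <- c(msgs, sprintf("column '%s' must be numeric", d$code[j]))
      else {
        obs <- x[!is.na(x)]
        if (any(!is.finite(obs)))
          msgs <- c(msgs, sprintf("column '%s' has non-finite values", d$code[j]))
        else {
          q <- d$quantity[j]
          if (q %in% c("peak_freq_hz", "min_freq_hz", "max_freq_hz",
                       "duration_s") && any(obs < 0))
            msgs <- c(msgs, sprintf("column '%s': %s must be >= 0", d$code[j], q))
          if (q %in% c("n_repeats", "n_notes", "n_syllables") &&
              any(obs < 0 | obs != round(obs)))
            msgs <- c(msgs, sprintf(
              "column '%s': counts must be non-negative integers", d$code[j]))
          if (q == "proportion_pct" && any(obs < 0 | obs > 100))
            msgs <- c(msgs, sprintf(
              "column '%s': proportion must lie in [0, 100]", d$code[j]))
        }
      }
    } else {
      if (!is.character(x))
        msgs <- c(msgs, sprintf("column '%s' must be character", d$code[j]))
      else if (!all(x[!is.na(x)] %in% slurLevels()))
        msgs <- c(msgs, sprintf("column '%s': slur values must be in {U, D}",
                                d$code[j]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SongDissimilarity: pairwise Gower dissimilarities
#'
#' Symmetric matrix of Gower dissimilarities in [0, 1] between individuals,
#' with the per-numeric-feature observed ranges used for scaling.  An entry
#' is \code{NA} when two individuals share no co-observed feature.
#'
#' @slot matrix symmetric numeric matrix, zero diagonal, dimnames = record ids.
#' @slot featureRanges named numeric vector: observed max - min of each
#'   numeric feature over the exact table the matrix was built from.
#' @export
setClass("SongDissimilarity",
  slots = c(matrix = "matrix", featureRanges = "numeric"))

setValidity("SongDissimilarity", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("matrix must carry identical row/column record ids")
  if (any(abs(diag(m)) > 1e-12, na.rm = TRUE)) return("diagonal must be zero")
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    return("matrix must be symmetric")
  ok <- m[!is.na(m)]
  if (any(ok < -1e-12 | ok > 1 + 1e-12))
    return("defined entries must lie in [0, 1]")
  TRUE
})

#' PamResult: partitioning-around-medoids clustering of a dissimilarity matrix
#'
#' @slot k number of clusters.
#' @slot medoids integer indices of the medoid individuals (sorted).
#' @slot clustering integer cluster assignment per individual (1..k); each
#'   medoid is assigned to its own cluster.
#' @slot totalCost sum of dissimilarities of every individual to its medoid.
#' @slot silhouette per-individual silhouette width s(i) in [-1, 1]
#'   (length 0 when k = 1, where the silhouette is undefined).
#' @slot avgSilWidth mean silhouette width (NA when k = 1).
#' @export
setClass("PamResult",
  slots = c(k = "integer", medoids = "integer", clustering = "integer",
            totalCost = "numeric", silhouette = "numeric",
            avgSilWidth = "numeric"))

setValidity("PamResult", function(object) {
  if (length(object@medoids) != object@k)
    return("number of medoids must equal k")
  if (!all(object@clustering[object@medoids] == seq_len(object@k)))
    return("each medoid must be assigned to its own cluster")
  if (!setequal(unique(object@clustering), seq_len(object@k)))
    return("clusters must be non-empty and labelled 1..k")
  TRUE
})

#' KSelection: silhouette-guided choice of the number of clusters
#'
#' Average silhouette width (ASW) profile over a scanned k range, the k that
#' maximises it, and a weak-structure flag: when even the best ASW falls
#' below \code{threshold}, the data are reported as a single cluster
#' (selectedK = 1) with \code{weakStructure = TRUE}.
#'
#' @slot aswByK named numeric: ASW per scanned k.
#' @slot selectedK selected number of clusters.
#' @slot weakStructure TRUE when max ASW < threshold.
#' @slot threshold the weak-structure ASW threshold used.
#' @slot fits list of \code{PamResult} per scanned k (names = k).
#' @export
setClass("KSelection",
  slots = c(aswByK = "numeric", selectedK = "integer",
            weakStructure = "logical", threshold = "numeric", fits = "list"))

#' MixedPCAResult: principal components of a mixed numeric/categorical table
#'
#' @slot eigenvalues non-increasing, non-negative eigenvalues; their sum
#'   equals \code{totalInertia} = #numeric variables + sum(levels - 1) over
#'   categorical variables.
#' @slot pctVariance eigenvalue / totalInertia * 100 per component.
#' @slot scores individuals x components matrix of component scores.
#' @slot loadings encoded-column x components matrix: for numeric variables
#'   the correlation-type loading; for categorical level-indicator columns
#'   the analogous scaled-column loading.
#' @slot squaredLoadings feature x components matrix of squared loadings
#'   aggregated per original feature (levels of a categorical summed).
#' @slot totalInertia total inertia of the encoded table.
#' @export
setClass("MixedPCAResult",
  slots = c(eigenvalues = "numeric", pctVariance = "numeric",
            scores = "matrix", loadings = "matrix",
            squaredLoadings = "matrix", totalInertia = "numeric"))

#' PermutationResult: Monte Carlo within/between dissimilarity comparison
#'
#' @slot comparison label "A_vs_B" of the two dissimilarity categories
#'   compared (among within_east, within_west, between).
#' @slot observed observed difference of category means, mean(A) - mean(B).
#' @slot B number of Monte Carlo label permutations.
#' @slot pRaw permutation p-value, (b + 1)/(B + 1).
#' @slot alternative "greater" or "two.sided".
#' @slot seed the seed that reproduces the permutation stream.
#' @export
setClass("PermutationResult",
  slots = c(comparison = "character", observed = "numeric", B = "integer",
            pRaw = "numeric", alternative = "character", seed = "integer"))

#' DeltaPResult: joint-CDF phenotypic divergence score
#'
#' @slot deltaP Euclidean distance between the two populations' vectors of
#'   per-feature median percentile coordinates (0-100 scale).
#' @slot coordinates 2 x featuresUsed matrix of percentile coordinates
#'   (rows = the two populations).
#' @slot hedgesG per-feature Hedge's g (population A vs B).
#' @slot featuresUsed codes of the features entering the score.
#' @slot featuresDropped codes dropped (unobserved in a population, or
#'   categorical when categorical features are excluded).
#' @export
setClass("DeltaPResult",
  slots = c(deltaP = "numeric", coordinates = "matrix", hedgesG = "numeric",
            featuresUsed = "character", featuresDropped = "character"))

#' PairReport: full between-taxa analysis of one east/west pair
#'
#' @slot inputs list: n per taxon, shared feature codes, dropped codes.
#' @slot gowerSummary list: mean/max dissimilarity, n undefined entries.
#' @slot kSelection \code{KSelection} on the pooled table.
#' @slot clustering \code{PamResult} at the selected k (k >= 2), or the
#'   k = 1 assignment when structure is weak.
#' @slot pca list: pctVariance of the leading components and top loadings.
#' @slot permutation list of three \code{PermutationResult} plus adjusted
#'   p-values (BH and Bonferroni) and the Bonferroni family size.
#' @slot deltaP \code{DeltaPResult} east vs west.
#' @slot concordance cluster-vs-taxon agreement fraction.
#' @slot seed integer seed stamp.
#' @export
setClass("PairReport",
  slots = c(inputs = "list", gowerSummary = "list", kSelection = "KSelection",
            clustering = "PamResult", pca = "list", permutation = "list",
            deltaP = "DeltaPResult", concordance = "numeric",
            seed = "integer"))

#' WithinReport: within-taxon variant screen
#'
#' @slot kSelection \code{KSelection} on the taxon's table.
#' @slot pca list: pctVariance and top-loading feature of PC1.
#' @slot topFeature code of the highest-loading feature on PC1.
#' @slot tTest list: t, df, p for the top feature between the two largest
#'   clusters (NULL when structure is weak).
#' @slot concordance cluster-vs-region agreement fraction (NA when not
#'   evaluated).
#' @slot variantCall TRUE only when clustering is non-weak (k >= 2) AND the
#'   cluster/region concordance exceeds the configured threshold.
#' @slot seed integer seed stamp.
#' @export
setClass("WithinReport",
  slots = c(kSelection = "KSelection", pca = "list", topFeature = "character",
            tTest = "list", concordance = "numeric", variantCall = "logical",
            seed = "integer"))
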