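## Gower dissimilarity over mixed numeric/categorical features with
## pairwise omission of missing cells.  The dissimilarity between two
## individuals is the mean, over features observed in BOTH, of
##   numeric:      |x_i - x_j| / range(feature)
##   categorical:  0 if equal, 1 if different
## so every defined entry lies in [0, 1].  Constant (zero-range) numeric
## features are uninformative and enter neither numerator nor denominator.

#' Gower dissimilarity between two rows
#'
#' Single-pair form of \code{\link{gowerMatrix}}, mostly useful for
#' inspecting how one comparison is composed.  Features missing in either
#' row are omitted and the denominator renormalised to the co-observed
#' feature count; if no feature is co-observed the result is \code{NA}.
#'
#' @param rowI,rowJ lists/vectors of cell values sharing one feature order.
#' @param ranges numeric vector of per-feature ranges (ignored entries for
#'   categorical features); zero-range features are skipped.
#' @param dtypes character vector, \code{"numeric"} or \code{"categorical"}
#'   per feature.
#' @return Dissimilarity in [0, 1], or \code{NA} if undefined.
#' @examples
#' gowerPair(list(1, "U"), list(3, "D"), ranges = c(4, NA),
#'           dtypes = c("numeric", "categorical"))  # (2/4 + 1)/2 = 0.75
#' @export
gowerPair <- function(rowI, rowJ, ranges, dtypes) {
  num <- 0; den <- 0L
  for (f in seq_along(dtypes)) {
    xi <- rowI[[f]]; xj <- rowJ[[f]]
    if (is.na(xi) || is.na(xj)) next
    if (dtypes[f] == "numeric") {
      if (!is.na(ranges[f]) && ranges[f] > 0) {
        num <- num + abs(xi - xj) / ranges[f]
        den <- den + 1L
      }                         # zero-range feature: contributes nothing
    } else {
      num <- num + as.numeric(xi != xj)
      den <- den + 1L
    }
  }
  if (den == 0L) NA_real_ else num / den
}

#' Pairwise Gower dissimilarity matrix of a feature table
#'
#' Computes all pairwise Gower dissimilarities over the table's features,
#' omitting missing cells pairwise.  Numeric features are scaled by their
#' observed range over exactly the table passed in, so a pooled east+west
#' table and a single-taxon table use different scalings by design.
#'
#' @param x a \code{SongFeatureTable} with at least 2 individuals.
#' @return A \code{\linkS4class{SongDissimilarity}}.
#' @export
gowerMatrix <- function(x) {
  v <- featureValues(x); d <- descriptors(x)
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 individuals for a dissimilarity matrix")
  ranges <- vapply(seq_len(ncol(v)), function(j) {
    if (d$dtype[j] != "numeric") return(NA_real_)
    obs <- v[[j]][!is.na(v[[j]])]
    if (length(obs) == 0L) NA_real_ else max(obs) - min(obs)
  }, 0)
  names(ranges) <- d$code
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (j in seq_len(ncol(v))) {
    col <- v[[j]]
    obs <- !is.na(col)
    pairObs <- tcrossprod(obs * 1)          # 1 where both observed
    if (d$dtype[j] == "numeric") {
      if (is.na(ranges[j]) || ranges[j] == 0) next
      z <- ifelse(obs, col, 0)
      diff <- abs(outer(z, z, "-")) / ranges[j]
      num <- num + diff * pairObs
      den <- den + pairObs
    } else {
      cf <- ifelse(obs, col, "")
      neq <- outer(cf, cf, "!=") * 1
      num <- num + neq * pairObs
      den <- den + pairObs
    }
  }
  m <- ifelse(den > 0, num / pmax(den, 1L), NA_real_)
  diag(m) <- 0
  dimnames(m) <- list(individualIds(x), individualIds(x))
  if (all(is.na(m[upper.tri(m)])))
    stop("all pairwise dissimilarities are undefined (no co-observed features)")
  new("SongDissimilarity", matrix = m, featureRanges = ranges)
}

#' @rdname SongDissimilarity-accessors
#' @export
setMethod("dissimMatrix", "SongDissimilarity", function(x) x@matrix)

#' Accessors for SongDissimilarity
#'
#' \code{dissimMatrix} returns the symmetric matrix; \code{featureRanges}
#' the per-numeric-feature ranges used for scaling.
#' @param x a \code{SongDissimilarity}.
#' @name SongDissimilarity-accessors
#' @aliases dissimMatrix featureRanges
NULL

#' @rdname SongDissimilarity-accessors
#' @export
setMethod("featureRanges", "SongDissimilarity", function(x) x@featureRanges)

#' @export
setMethod("dim", "SongDissimilarity", function(x) dim(x@matrix))

setMethod("show", "SongDissimilarity", function(object) {
  m <- object@matrix
  up <- m[upper.tri(m)]
  cat("SongDissimilarity:", nrow(m), "individuals\n")
  cat(sprintf("  defined entries: %d/%d, mean %.3f, max %.3f\n",
              sum(!is.na(up)), length(up),
              mean(up, na.rm = TRUE), max(up, na.rm = TRUE)))
})

#' Write a dissimilarity matrix to CSV
#'
#' Square layout with record ids as first column and header.
#' @param x a \code{SongDissimilarity}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDissimilarity <- function(x, path) {
  utils::write.csv(as.data.frame(x@matrix), path, row.names = TRUE,
                   na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
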