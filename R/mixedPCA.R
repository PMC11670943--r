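## Principal component analysis for mixed numeric/categorical tables,
## in the FAMD / PCAmix tradition: numeric columns standardised to unit
## (population, 1/n) variance; categorical variables one-hot encoded,
## centred, and each level column scaled by 1 / sqrt(level proportion);
## spectral decomposition of the 1/n-weighted cross-product.  With an
## all-numeric table this reduces exactly to PCA of the correlation
## matrix; a single m-level categorical reduces to its multiple
## correspondence analysis with total inertia m - 1.

#' Impute missing cells for mixed PCA
#'
#' Replaces missing numeric cells by the column mean of the observed
#' values.  Missing categorical cells are kept as explicit markers that
#' contribute zero to every level-indicator column when the table is
#' encoded (an all-zeros indicator row block).  The input table is left
#' untouched.
#'
#' @param x a \code{SongFeatureTable}.
#' @return A \code{SongFeatureTable} with numeric columns complete.
#' @export
imputeForPCA <- function(x) {
  v <- featureValues(x); d <- descriptors(x)
  for (j in seq_len(ncol(v))) {
    if (d$dtype[j] != "numeric") next
    col <- v[[j]]
    if (all(is.na(col)))
      stop("column ", sQuote(d$code[j]),
           " is entirely missing; drop it before PCA")
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    v[[j]] <- col
  }
  out <- x
  out@values <- v
  out
}

## Encode a (numeric-complete) table into the weighted matrix Z whose
## 1/n cross-product is decomposed, plus bookkeeping per encoded column.
.encodeMixed <- function(x) {
  v <- featureValues(x); d <- descriptors(x)
  n <- nrow(v)
  cols <- list(); colFeature <- character(); colName <- character()
  inertia <- 0
  for (j in seq_len(ncol(v))) {
    code <- d$code[j]
    if (d$dtype[j] == "numeric") {
      col <- v[[j]]
      mu <- mean(col)
      sdp <- sqrt(mean((col - mu)^2))       # 1/n variance
      if (sdp == 0)
        stop("numeric column ", sQuote(code),
             " is constant; drop it before PCA")
      cols[[length(cols) + 1L]] <- (col - mu) / sdp
      colFeature <- c(colFeature, code); colName <- c(colName, code)
      inertia <- inertia + 1
    } else {
      lev <- sort(unique(v[[j]][!is.na(v[[j]])]))
      if (length(lev) < 2L)
        stop("categorical column ", sQuote(code),
             " has fewer than 2 observed levels; drop it before PCA")
      for (s in lev) {
        ind <- as.numeric(!is.na(v[[j]]) & v[[j]] == s)  # missing -> 0
        p <- mean(ind)
        cols[[length(cols) + 1L]] <- (ind - p) / sqrt(p)
        colFeature <- c(colFeature, code)
        colName <- c(colName, paste0(code, "=", s))
      }
      inertia <- inertia + length(lev) - 1L
    }
  }
  Z <- do.call(cbind, cols)
  dimnames(Z) <- list(rownames(v), colName)
  list(Z = Z, colFeature = colFeature, nominalInertia = inertia)
}

#' Mixed-data principal component analysis
#'
#' Fits the FAMD-family PCA described above.  Missing cells are imputed
#' first via \code{\link{imputeForPCA}} (numeric: column mean;
#' categorical: all-zero indicators).  Each component's loading vector is
#' flipped so its largest-magnitude entry is positive, making signs
#' deterministic.
#'
#' @param x a \code{SongFeatureTable}.
#' @param nComponents number of leading components for which scores and
#'   loadings are returned (default: all).
#' @return A \code{\linkS4class{MixedPCAResult}}.  \code{eigenvalues}
#'   always covers the full spectrum so that their sum can be checked
#'   against the total inertia (#numeric + sum(levels - 1) for tables with
#'   complete categorical columns).
#' @export
mixedPCA <- function(x, nComponents = NULL) {
  if (nrow(featureValues(x)) < 2L) stop("need at least 2 individuals")
  enc <- .encodeMixed(imputeForPCA(x))
  Z <- enc$Z
  n <- nrow(Z); p <- ncol(Z)
  if (p < 2L) stop("need at least 2 encoded columns")
  C <- crossprod(Z) / n
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  ncomp <- if (is.null(nComponents)) p else min(as.integer(nComponents), p)
  V <- eig$vectors[, seq_len(ncomp), drop = FALSE]
  ## deterministic sign: largest-|entry| of each loading vector positive
  for (c in seq_len(ncomp)) {
    i <- which.max(abs(V[, c]))
    if (V[i, c] < 0) V[, c] <- -V[, c]
  }
  scores <- Z %*% V
  loadings <- sweep(V, 2L, sqrt(lambda[seq_len(ncomp)]), "*")
  dimnames(loadings) <- list(colnames(Z), paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(Z), paste0("PC", seq_len(ncomp)))
  sq <- rowsum(loadings^2, group = enc$colFeature, reorder = FALSE)
  totalInertia <- sum(diag(C))
  new("MixedPCAResult",
      eigenvalues = lambda,
      pctVariance = 100 * lambda / totalInertia,
      scores = scores, loadings = loadings, squaredLoadings = sq,
      totalInertia = totalInertia)
}

#' Highest-loading feature of a component
#'
#' Returns the feature whose squared loading (levels of a categorical
#' variable summed) on the given component is largest; ties break to the
#' earliest column in table order.
#'
#' @param x a \code{MixedPCAResult}.
#' @param component component index (default 1).
#' @return List with \code{code} and \code{squaredLoading}.
#' @export
topLoadingFeature <- function(x, component = 1L) {
  stopifnot(is(x, "MixedPCAResult"))
  if (component < 1L || component > ncol(x@squaredLoadings))
    stop("component index out of range")
  sl <- x@squaredLoadings[, component]
  i <- which.max(sl)                        # ties -> first in table order
  list(code = rownames(x@squaredLoadings)[i],
       squaredLoading = unname(sl[i]))
}

#' Accessors for MixedPCAResult
#'
#' \code{eigenvalues}, \code{pctVariance} (per cent of total inertia per
#' component) and \code{componentScores} (individuals x components).
#' @param x a \code{MixedPCAResult}.
#' @name MixedPCAResult-accessors
#' @aliases eigenvalues pctVariance componentScores
NULL

#' @rdname MixedPCAResult-accessors
#' @export
setMethod("eigenvalues", "MixedPCAResult", function(x) x@eigenvalues)

#' @rdname MixedPCAResult-accessors
#' @export
setMethod("pctVariance", "MixedPCAResult", function(x) x@pctVariance)

#' @rdname MixedPCAResult-accessors
#' @export
setMethod("componentScores", "MixedPCAResult", function(x) x@scores)

setMethod("show", "MixedPCAResult", function(object) {
  k <- min(4L, length(object@pctVariance))
  cat("MixedPCAResult: total inertia", format(object@totalInertia), "\n")
  cat("  % variance:",
      paste(sprintf("PC%d %.2f", seq_len(k), object@pctVariance[seq_len(k)]),
            collapse = ", "), "\n")
})
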