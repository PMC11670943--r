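## Construction, IO, accessors and validation for SongFeatureTable.

#' Construct a SongFeatureTable
#'
#' @param values data.frame (or matrix) of measurements, one row per
#'   individual, column names being measurement codes.  Numeric columns for
#'   numeric quantities; character columns with levels \code{"U"}/\code{"D"}
#'   for slur.  \code{NA} marks missing cells.
#' @param taxon character vector of taxon labels (e.g. \code{"east"} /
#'   \code{"west"}), recycled if length 1.
#' @param latitude,longitude optional decimal-degree coordinates per
#'   individual.
#' @param sex optional character vector.
#' @param ids record ids; defaults to rownames of \code{values} or
#'   \code{ind1..indn}.
#' @return A validated \code{\linkS4class{SongFeatureTable}}.
#' @examples
#' tab <- SongFeatureTable(
#'   data.frame(`1` = c(1.2, 1.5), `8a` = c("U", "D"), check.names = FALSE),
#'   taxon = c("east", "west"))
#' featureCodes(tab)
#' @export
SongFeatureTable <- function(values, taxon, latitude = NULL, longitude = NULL,
                             sex = NULL, ids = NULL) {
  values <- as.data.frame(values, check.names = FALSE)
  n <- nrow(values)
  if (is.null(ids))
    ids <- if (!is.null(rownames(values)) &&
               !identical(rownames(values), as.character(seq_len(n))))
      rownames(values) else paste0("ind", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- parseMeasurementCode(colnames(values))
  colnames(values) <- desc$code   # normalised (lower-case syllable)
  for (j in seq_len(ncol(values))) {
    values[[j]] <- if (desc$dtype[j] == "numeric") as.numeric(values[[j]])
                   else as.character(values[[j]])
  }
  rownames(values) <- ids
  sdat <- data.frame(taxon = as.character(rep_len(taxon, n)),
                     row.names = ids, stringsAsFactors = FALSE)
  sdat$latitude <- if (is.null(latitude)) NA_real_ else as.numeric(latitude)
  sdat$longitude <- if (is.null(longitude)) NA_real_ else as.numeric(longitude)
  sdat$sex <- if (is.null(sex)) NA_character_ else as.character(sex)
  new("SongFeatureTable", values = values, descriptors = desc,
      sampleData = sdat)
}

#' Read a song feature table from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row of measurement
#' codes plus metadata columns.  Missing cells may be empty or \code{"NA"}.
#'
#' @param path path to the CSV file.
#' @param taxonColumn name of the taxon metadata column (default
#'   \code{"taxon"}).
#' @param metaColumns further column names to treat as metadata rather than
#'   measurements; \code{"id"}, \code{"latitude"}, \code{"longitude"} and
#'   \code{"sex"} are always recognised when present.
#' @return A validated \code{\linkS4class{SongFeatureTable}}.
#' @export
readFeatureTable <- function(path, taxonColumn = "taxon",
                             metaColumns = character()) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  meta <- unique(c("id", taxonColumn, "latitude", "longitude", "sex",
                   metaColumns))
  meta <- intersect(meta, colnames(raw))
  if (!taxonColumn %in% meta)
    stop("taxon column ", sQuote(taxonColumn), " not found in ", path)
  codes <- setdiff(colnames(raw), meta)
  if (length(codes) == 0L) stop("no measurement columns in ", path)
  desc <- parseMeasurementCode(codes)
  vals <- raw[, codes, drop = FALSE]
  for (j in seq_along(codes)) {
    if (desc$dtype[j] == "numeric") {
      x <- vals[[j]]
      num <- suppressWarnings(as.numeric(x))
      badcell <- !is.na(x) & is.na(num)
      if (any(badcell))
        stop("non-numeric content in numeric column ", sQuote(codes[j]),
             ": ", sQuote(x[which(badcell)[1L]]))
      vals[[j]] <- num
    }
  }
  SongFeatureTable(vals,
                   taxon = raw[[taxonColumn]],
                   latitude = if ("latitude" %in% meta)
                     suppressWarnings(as.numeric(raw$latitude)) else NULL,
                   longitude = if ("longitude" %in% meta)
                     suppressWarnings(as.numeric(raw$longitude)) else NULL,
                   sex = if ("sex" %in% meta) raw$sex else NULL,
                   ids = if ("id" %in% meta) raw$id else NULL)
}

#' Write a song feature table to CSV
#'
#' Inverse of \code{\link{readFeatureTable}}: metadata columns first
#' (\code{id}, \code{taxon}, and coordinates/sex when any value is present),
#' then the measurement columns in table order.  Missing cells are written
#' as \code{"NA"}.
#'
#' @param x a \code{SongFeatureTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  s <- sampleData(x)
  out <- data.frame(id = rownames(s), taxon = s$taxon,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (any(!is.na(s$latitude))) out$latitude <- s$latitude
  if (any(!is.na(s$longitude))) out$longitude <- s$longitude
  if (any(!is.na(s$sex))) out$sex <- s$sex
  out <- cbind(out, featureValues(x))
  utils::write.csv(out, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a feature table and summarise its columns
#'
#' Report-only quality check: per-feature missingness fraction, dtype, and
#' observed range (min/max for numeric features, level count for
#' categorical), flagging constant and all-missing columns.
#'
#' @param x a \code{SongFeatureTable}.
#' @return data.frame with one row per feature: \code{code}, \code{dtype},
#'   \code{missing_frac}, \code{min}, \code{max}, \code{n_levels},
#'   \code{constant}, \code{all_missing}.
#' @export
validateFeatureTable <- function(x) {
  v <- featureValues(x); d <- descriptors(x)
  rep <- data.frame(code = d$code, dtype = d$dtype,
                    missing_frac = vapply(v, function(col) mean(is.na(col)), 0),
                    min = NA_real_, max = NA_real_, n_levels = NA_integer_,
                    constant = FALSE, all_missing = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) {
    obs <- v[[j]][!is.na(v[[j]])]
    if (length(obs) == 0L) { rep$all_missing[j] <- TRUE; next }
    if (d$dtype[j] == "numeric") {
      rep$min[j] <- min(obs); rep$max[j] <- max(obs)
      rep$constant[j] <- rep$min[j] == rep$max[j]
    } else {
      rep$n_levels[j] <- length(unique(obs))
      rep$constant[j] <- rep$n_levels[j] == 1L
    }
  }
  rownames(rep) <- rep$code
  rep
}

## ---- accessors ------------------------------------------------------------

#' Accessors for SongFeatureTable
#'
#' \code{featureValues} returns the individuals-by-features data.frame;
#' \code{featureCodes} the measurement codes; \code{descriptors} the parsed
#' code descriptors; \code{sampleData} the per-individual metadata;
#' \code{taxonLabels} the taxon label vector; \code{individualIds} the
#' record ids.
#'
#' @param x a \code{SongFeatureTable}.
#' @name SongFeatureTable-accessors
#' @aliases featureValues featureCodes descriptors sampleData taxonLabels
#'   individualIds
NULL

#' @rdname SongFeatureTable-accessors
#' @export
setMethod("featureValues", "SongFeatureTable", function(x) x@values)

#' @rdname SongFeatureTable-accessors
#' @export
setMethod("featureCodes", "SongFeatureTable", function(x) x@descriptors$code)

#' @rdname SongFeatureTable-accessors
#' @export
setMethod("descriptors", "SongFeatureTable", function(x) x@descriptors)

#' @rdname SongFeatureTable-accessors
#' @export
setMethod("sampleData", "SongFeatureTable", function(x) x@sampleData)

#' @rdname SongFeatureTable-accessors
#' @export
setMethod("taxonLabels", "SongFeatureTable", function(x) x@sampleData$taxon)

#' @rdname SongFeatureTable-accessors
#' @export
setMethod("individualIds", "SongFeatureTable", function(x) rownames(x@values))

#' @export
setMethod("dim", "SongFeatureTable", function(x) dim(x@values))

#' Subset a SongFeatureTable
#'
#' \code{x[i, j]} subsets individuals (\code{i}) and/or features (\code{j},
#' by position or measurement code), keeping metadata and descriptors in
#' step.
#' @param x a \code{SongFeatureTable}.
#' @param i,j individual and feature indices.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "SongFeatureTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  if (is.character(j)) j <- match(j, x@descriptors$code)
  if (anyNA(j)) stop("unknown measurement code in subset")
  new("SongFeatureTable",
      values = x@values[i, j, drop = FALSE],
      descriptors = x@descriptors[j, , drop = FALSE],
      sampleData = x@sampleData[i, , drop = FALSE])
})

setMethod("show", "SongFeatureTable", function(object) {
  d <- dim(object)
  tab <- table(taxonLabels(object))
  cat("SongFeatureTable:", d[1L], "individuals x", d[2L], "features\n")
  cat("  taxa:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  cat("  features:", paste(utils::head(featureCodes(object), 8L),
                           collapse = " "),
      if (d[2L] > 8L) "..." else "", "\n")
  miss <- mean(is.na(as.matrix(object@values)))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
})

#' Combine two feature tables sharing a schema
#'
#' Row-binds two tables after reconciling their feature sets by code
#' intersection (codes present in only one table are dropped, with a
#' message).  Used to pool an east and a west table for between-taxa
#' analyses.
#'
#' @param x,y \code{SongFeatureTable} objects with disjoint record ids.
#' @return A pooled \code{SongFeatureTable}; attribute
#'   \code{"droppedCodes"} lists codes not shared by both tables.
#' @export
poolFeatureTables <- function(x, y) {
  shared <- intersect(featureCodes(x), featureCodes(y))
  if (length(shared) == 0L) stop("the two tables share no measurement codes")
  dropped <- setdiff(union(featureCodes(x), featureCodes(y)), shared)
  if (length(dropped))
    message("dropping codes not shared by both tables: ",
            paste(dropped, collapse = ", "))
  xs <- x[, shared]; ys <- y[, shared]
  if (length(intersect(individualIds(xs), individualIds(ys))))
    stop("record ids overlap between the two tables")
  out <- new("SongFeatureTable",
             values = rbind(xs@values, ys@values),
             descriptors = xs@descriptors,
             sampleData = rbind(xs@sampleData, ys@sampleData))
  validObject(out)
  attr(out, "droppedCodes") <- dropped
  out
}
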