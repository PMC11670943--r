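#' @rdname SongFeatureTable-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname SongFeatureTable-accessors
#' @export
setGeneric("featureCodes", function(x) standardGeneric("featureCodes"))

#' @rdname SongFeatureTable-accessors
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' @rdname SongFeatureTable-accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname SongFeatureTable-accessors
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))

#' @rdname SongFeatureTable-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname SongDissimilarity-accessors
#' @export
setGeneric("dissimMatrix", function(x) standardGeneric("dissimMatrix"))

#' @rdname SongDissimilarity-accessors
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))

#' @rdname PamResult-accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname PamResult-accessors
#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))

#' @rdname PamResult-accessors
#' @export
setGeneric("avgSilWidth", function(x) standardGeneric("avgSilWidth"))

#' @rdname KSelection-accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname KSelection-accessors
#' @export
setGeneric("weakStructure", function(x) standardGeneric("weakStructure"))

#' @rdname MixedPCAResult-accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname MixedPCAResult-accessors
#' @export
setGeneric("pctVariance", function(x) standardGeneric("pctVariance"))

#' @rdname MixedPCAResult-accessors
#' @export
setGeneric("componentScores", function(x) standardGeneric("componentScores"))

#' @rdname DeltaPResult-accessors
#' @export
setGeneric("deltaPScore", function(x) standardGeneric("deltaPScore"))

#' @rdname PermutationResult-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname WithinReport-accessors
#' @export
setGeneric("variantCall", function(x) standardGeneric("variantCall"))
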