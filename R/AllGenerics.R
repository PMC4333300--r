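#' Accessors for RankingDataset
#'
#' @param x a \linkS4class{RankingDataset}.
#' @return \code{targets}, \code{compounds} and \code{affinities} return the
#'   corresponding data.frame; \code{descriptors} the compound descriptor
#'   matrix (rows = compounds).
#' @name dataset-accessors
#' @aliases targets compounds affinities descriptors
NULL

#' @rdname dataset-accessors
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))
#' @rdname dataset-accessors
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))
#' @rdname dataset-accessors
#' @export
setGeneric("affinities", function(x) standardGeneric("affinities"))
#' @rdname dataset-accessors
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' @rdname dataset-accessors
setMethod("targets", "RankingDataset", function(x) x@targets)
#' @rdname dataset-accessors
setMethod("compounds", "RankingDataset", function(x) x@compounds)
#' @rdname dataset-accessors
setMethod("affinities", "RankingDataset", function(x) x@affinities)
#' @rdname dataset-accessors
setMethod("descriptors", "RankingDataset", function(x) x@descriptors)

#' Score feature vectors with a fitted ranker
#'
#' @param model a fitted \linkS4class{RankerModel}.
#' @param X numeric matrix (rows = instances) or a single feature vector.
#' @return numeric vector of ranking scores, one per row of \code{X}.
#' @export
setGeneric("scoreFeatures", function(model, X) standardGeneric("scoreFeatures"))
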