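# Accessor generics and methods; slot access stays internal.

#' Extract the encounter-by-feature matrix
#'
#' Returns the standardized N x F matrix (encounters in rows) used by the
#' clustering and mixture-model stages.
#'
#' @param x A \linkS4class{PhysioFeatureSet}.
#' @return Numeric N x F matrix with encounter ids as row names.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "PhysioFeatureSet", function(x) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' Standardization parameters of a feature set or model
#'
#' @param x A \linkS4class{PhysioFeatureSet} or
#'   \linkS4class{PhysiotypeModel}.
#' @return Data frame with columns \code{feature}, \code{mean}, \code{sd}.
#' @export
setGeneric("standardization", function(x) standardGeneric("standardization"))

#' @rdname standardization
#' @export
setMethod("standardization", "PhysioFeatureSet", function(x) {
  S4Vectors::metadata(x)$standardization
})

#' @rdname standardization
#' @export
setMethod("standardization", "PhysiotypeModel", function(x) x@standardization)

#' Selected number of clusters of a consensus run
#'
#' @param x A \linkS4class{ConsensusResult}.
#' @return Integer scalar.
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname selectedK
#' @export
setMethod("selectedK", "ConsensusResult", function(x) x@selectedK)

#' Final cluster labels of a consensus run
#'
#' @param x A \linkS4class{ConsensusResult}.
#' @return Integer vector of length N.
#' @export
setGeneric("finalLabels", function(x) standardGeneric("finalLabels"))

#' @rdname finalLabels
#' @export
setMethod("finalLabels", "ConsensusResult", function(x) x@finalLabels)

#' Consensus matrix for one value of k
#'
#' @param x A \linkS4class{ConsensusResult}.
#' @param k Number of clusters; defaults to the selected k.
#' @return N x N symmetric matrix with entries in [0, 1].
#' @export
setGeneric("consensusMatrixFor",
           function(x, k) standardGeneric("consensusMatrixFor"))

#' @rdname consensusMatrixFor
#' @export
setMethod("consensusMatrixFor", "ConsensusResult", function(x, k) {
  if (missing(k)) k <- x@selectedK
  M <- x@consensusMatrices[[as.character(k)]]
  if (is.null(M)) stop("no consensus matrix stored for k = ", k)
  M
})

#' Centroids of a physiotype model
#'
#' @param x A \linkS4class{PhysiotypeModel}.
#' @return k x F matrix in standardized feature space, rows named by
#'   physiotype letter.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname centroids
#' @export
setMethod("centroids", "PhysiotypeModel", function(x) x@centroids)

#' Posterior membership probabilities of a mixture fit
#'
#' @param x A \linkS4class{GmmFit}.
#' @return N x k matrix of responsibilities (rows sum to 1).
#' @export
setGeneric("responsibilities", function(x) standardGeneric("responsibilities"))

#' @rdname responsibilities
#' @export
setMethod("responsibilities", "GmmFit", function(x) x@responsibilities)
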