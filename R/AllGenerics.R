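#' @import methods
NULL

#' @rdname relAbundance
#' @export
setGeneric("relAbundance", function(x, ...) standardGeneric("relAbundance"))

#' @rdname rarefyCounts
#' @export
setGeneric("rarefyCounts", function(x, depth, seed = NULL, ...)
  standardGeneric("rarefyCounts"))

#' @rdname brayCurtis
#' @export
setGeneric("brayCurtis", function(x, ...) standardGeneric("brayCurtis"))

#' @rdname uniFrac
#' @export
setGeneric("uniFrac", function(x, tree, weighted = FALSE, ...)
  standardGeneric("uniFrac"))

#' @rdname clusterCags
#' @export
setGeneric("clusterCags", function(x, ...) standardGeneric("clusterCags"))

#' @rdname cagAbundance
#' @export
setGeneric("cagAbundance", function(x, assignment, ...)
  standardGeneric("cagAbundance"))

#' @rdname sparsePartialNetwork
#' @export
setGeneric("sparsePartialNetwork", function(x, ...)
  standardGeneric("sparsePartialNetwork"))

#' @rdname lefseLite
#' @export
setGeneric("lefseLite", function(x, labels, ...) standardGeneric("lefseLite"))

#' @rdname adjustedLinearModels
#' @export
setGeneric("adjustedLinearModels", function(x, labels, covariates = NULL, ...)
  standardGeneric("adjustedLinearModels"))

#' Accessors for guildscope result objects
#'
#' Small generics exposing the slots of the S4 result classes without
#' direct slot access: cluster labels and chosen `k` of a
#' [CagAssignment], the edge table of a [PartialCorrelationNetwork], and
#' the AUC / confidence interval / curve of a [RocResult].
#'
#' @param x A guildscope result object.
#' @return `cagLabels`: named integer vector of cluster labels;
#'   `cagK`: integer; `networkEdges`: data.frame with columns
#'   `from`, `to`, `weight`; `aucValue`: numeric AUC; `aucCI`: numeric
#'   length-2 vector; `rocCurve`: data.frame with `threshold`,
#'   `sensitivity`, `specificity`.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("cagLabels", function(x) standardGeneric("cagLabels"))

#' @rdname result-accessors
#' @export
setGeneric("cagK", function(x) standardGeneric("cagK"))

#' @rdname result-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname result-accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname result-accessors
#' @export
setGeneric("aucCI", function(x) standardGeneric("aucCI"))

#' @rdname result-accessors
#' @export
setGeneric("rocCurve", function(x) standardGeneric("rocCurve"))
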