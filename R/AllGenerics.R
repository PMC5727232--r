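#' @rdname MotifPanel-class
#' @param x a `MotifPanel`.
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @rdname MotifPanel-class
#' @export
setGeneric("panelPatterns", function(x) standardGeneric("panelPatterns"))

#' @rdname MotifPanel-class
#' @export
setGeneric("patternWidth", function(x) standardGeneric("patternWidth"))

#' @rdname MotifPanel-class
#' @export
setGeneric("contextRule", function(x) standardGeneric("contextRule"))

#' @rdname panelCounts
#' @export
setGeneric("panelCounts", function(x, panel) standardGeneric("panelCounts"))

#' @rdname EnrichmentResult-class
#' @param x an `EnrichmentResult`.
#' @export
setGeneric("enrichmentFold", function(x) standardGeneric("enrichmentFold"))

#' @rdname ClusterDistribution-class
#' @param x a `ClusterDistribution`.
#' @export
setGeneric("clusterFractions", function(x) standardGeneric("clusterFractions"))

#' @rdname ClusterDistribution-class
#' @export
setGeneric("clusterTallies", function(x) standardGeneric("clusterTallies"))
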