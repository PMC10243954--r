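#' @import methods
NULL

#' Node names of a network
#'
#' @param x A [Network-class] object.
#' @return Character vector of node (gene) names.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge table of a network
#'
#' @param x A [Network-class] object.
#' @return A `data.frame` with columns `from`, `to`, `confidence`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Number of nodes
#' @param x A [Network-class] object.
#' @return Integer scalar.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges
#' @param x A [Network-class] object.
#' @return Integer scalar.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Convert to an igraph object
#'
#' @param x A [Network-class] object.
#' @return An `igraph` graph with vertex names and a `confidence` edge
#'   attribute.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Diffusion scores
#' @param x An [RWRResult-class] object.
#' @return Named numeric vector of per-node steady-state probabilities.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Separation index
#' @param x A [ProximityResult-class] object.
#' @return Numeric scalar `s_AB`.
#' @export
setGeneric("sAB", function(x) standardGeneric("sAB"))

#' Members of a gene set or complex
#' @param x A [GeneSet-class] or [MCODEComplex-class] object.
#' @return Character vector of gene symbols.
#' @export
setGeneric("members", function(x) standardGeneric("members"))
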