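## Graph construction, topology statistics, the two-times-median key-target
## screen, compound degree ranking and the transcription-factor subnetwork.
## Shortest-path quantities are computed on the unweighted graph:
## confidences gate which edges exist but do not weight paths.

#' Build a confidence-filtered network
#'
#' Keeps edges with confidence strictly greater than `minConfidence`
#' (default 0.4, the conventional medium-confidence STRING cutoff). When
#' `restrictTo` is given, only edges with both endpoints inside it are
#' kept and every permitted gene is retained as a node even if isolated.
#'
#' @param edges `data.frame` with columns `node_a`, `node_b`, `confidence`
#'   (as returned by [readEdgeList()]) or `from`, `to`, `confidence`.
#' @param minConfidence Strict lower bound on edge confidence.
#' @param restrictTo Optional character vector of permitted genes.
#' @return A [Network-class] object.
#' @export
buildNetwork <- function(edges, minConfidence = 0.4, restrictTo = NULL) {
  if (all(c("node_a", "node_b") %in% names(edges))) {
    edges <- data.frame(from = edges$node_a, to = edges$node_b,
                        confidence = edges$confidence)
  }
  edges$from <- canonicalizeSymbols(edges$from)
  edges$to <- canonicalizeSymbols(edges$to)
  keep <- edges$confidence > minConfidence
  if (!is.null(restrictTo)) {
    restrictTo <- canonicalizeSymbols(restrictTo)
    keep <- keep & edges$from %in% restrictTo & edges$to %in% restrictTo
  }
  Network(nodes = if (is.null(restrictTo)) character() else restrictTo,
          edges = edges[keep, , drop = FALSE])
}

#' Average node degree
#'
#' @param network A [Network-class] object with at least one node.
#' @return `2 * |E| / |V|`.
#' @export
#' @examples
#' net <- Network(edges = data.frame(from = "A", to = "B", confidence = 1))
#' averageDegree(net)  # 1
averageDegree <- function(network) {
  stopifnot(is(network, "Network"))
  if (numNodes(network) == 0) stop("empty network")
  2 * numEdges(network) / numNodes(network)
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient; nodes of degree
#' below 2 contribute zero.
#'
#' @param network A [Network-class] object with at least one node.
#' @return Numeric scalar in \[0, 1\].
#' @export
averageClustering <- function(network) {
  stopifnot(is(network, "Network"))
  if (numNodes(network) == 0) stop("empty network")
  cc <- igraph::transitivity(asIgraph(network), type = "local",
                             isolates = "zero")
  mean(cc)
}

#' Degree and betweenness centralities
#'
#' Exact degree and exact unnormalized shortest-path betweenness on the
#' unweighted graph (endpoints excluded from their own paths).
#'
#' @param network A [Network-class] object.
#' @return `data.frame` with columns `node`, `degree`, `betweenness`, one
#'   row per node in node order.
#' @export
centralities <- function(network) {
  stopifnot(is(network, "Network"))
  g <- asIgraph(network)
  data.frame(node = networkNodes(network),
             degree = as.integer(igraph::degree(g)),
             betweenness = igraph::betweenness(g, weights = NA,
                                               normalized = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Key-target screen: two times the median
#'
#' Selects nodes whose degree and betweenness both strictly exceed twice
#' the respective medians taken over all network nodes (isolated nodes
#' included).
#'
#' @param table Centrality table from [centralities()].
#' @return Sorted character vector of key-target genes (possibly empty).
#' @export
keyTargets <- function(table) {
  stopifnot(all(c("node", "degree", "betweenness") %in% names(table)))
  if (!nrow(table)) stop("centrality table is empty")
  keep <- table$degree > 2 * stats::median(table$degree) &
    table$betweenness > 2 * stats::median(table$betweenness)
  sort(table$node[keep])
}

#' Rank compounds by common-target degree
#'
#' The degree of a compound is the number of distinct common-target genes
#' it is associated with. Ranking is by degree descending with ties broken
#' by alias label ascending; compounds without common-target links rank
#' last with degree zero.
#'
#' @param assocs `data.frame` with columns `compound_id` and `gene`.
#' @param common Character vector of common-target genes.
#' @param aliases Alias table from [assignAliases()].
#' @return `data.frame` with columns `compound_id`, `label`, `degree`,
#'   sorted by rank.
#' @export
compoundDegreeRanking <- function(assocs, common, aliases) {
  common <- canonicalizeSymbols(common)
  assocs$gene <- canonicalizeSymbols(assocs$gene)
  hit <- assocs[assocs$gene %in% common, c("compound_id", "gene")]
  hit <- hit[!duplicated(hit), , drop = FALSE]
  deg <- table(factor(hit$compound_id, levels = aliases$compound_id))
  out <- data.frame(compound_id = aliases$compound_id,
                    label = aliases$label,
                    degree = as.integer(deg[aliases$compound_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcription-factor regulation subnetwork
#'
#' Restricts a regulator/target/mode table to pairs where both genes lie in
#' a given gene set and reports per-regulator out-degree.
#'
#' @param regulations `data.frame` with columns `regulator`, `target`,
#'   `mode` (values `activation`, `repression`, `unknown`).
#' @param genes Character vector of permitted genes.
#' @return List with `edges` (the kept rows) and `outDegree` (named
#'   integer vector, descending).
#' @export
tfSubnetwork <- function(regulations, genes) {
  ok <- c("activation", "repression", "unknown")
  bad <- setdiff(unique(regulations$mode), ok)
  if (length(bad))
    stop("unknown regulation mode(s): ", paste(bad, collapse = ", "))
  genes <- canonicalizeSymbols(genes)
  regulations$regulator <- canonicalizeSymbols(regulations$regulator)
  regulations$target <- canonicalizeSymbols(regulations$target)
  keep <- regulations$regulator %in% genes & regulations$target %in% genes
  edges <- regulations[keep, , drop = FALSE]
  rownames(edges) <- NULL
  od <- sort(table(edges$regulator), decreasing = TRUE)
  list(edges = edges,
       outDegree = stats::setNames(as.integer(od), names(od)))
}
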