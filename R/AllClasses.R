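#' Canonicalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted; identifiers from different sources are matched at the symbol
#' level only.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of canonical symbols.
#' @export
#' @examples
#' canonicalizeSymbols(c(" akt1", "Tp53 "))
canonicalizeSymbols <- function(x) {
  toupper(trimws(as.character(x)))
}

## ---------------------------------------------------------------------------
## Network
## ---------------------------------------------------------------------------

#' Undirected confidence-weighted gene network
#'
#' The substrate for every graph computation in the package: centrality and
#' key-target screening, MCODE complex detection, random-walk-with-restart
#' diffusion and the network proximity index. Nodes are canonical gene
#' symbols; edges are unordered pairs with an interaction confidence in
#' \[0, 1\] (STRING-style combined scores rescaled to the unit interval).
#'
#' @slot nodes Character vector of unique gene symbols.
#' @slot edges `data.frame` with columns `from`, `to` (character) and
#'   `confidence` (numeric in \[0, 1\]); no self-loops, no duplicate
#'   undirected pairs, all endpoints present in `nodes`.
#'
#' @seealso [Network()], [buildNetwork()], [asIgraph()]
#' @export
setClass("Network", representation(nodes = "character", edges = "data.frame"))

setValidity("Network", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "confidence") %in% names(e)))
    return("edges must have columns 'from', 'to', 'confidence'")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node names")
  if (nrow(e)) {
    if (any(e$from == e$to))
      msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate undirected edges")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoint not in node set")
    if (any(is.na(e$confidence)) ||
        any(e$confidence < 0) || any(e$confidence > 1))
      msg <- c(msg, "confidences must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Network
#'
#' @param nodes Character vector of gene symbols (canonicalized on input).
#'   Nodes that appear only in `edges` are added automatically, so isolated
#'   nodes can be declared explicitly.
#' @param edges `data.frame` with columns `from`, `to`, `confidence`
#'   (defaults to 1 when absent). Symbols are canonicalized; each unordered
#'   pair must occur at most once.
#' @return A validated [Network-class] object.
#' @export
#' @examples
#' net <- Network(edges = data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                   confidence = c(0.9, 0.7)))
#' numNodes(net)
Network <- function(nodes = character(), edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        confidence = numeric())
  edges <- as.data.frame(edges)
  if (!"confidence" %in% names(edges) && nrow(edges))
    edges$confidence <- 1
  if (nrow(edges)) {
    edges$from <- canonicalizeSymbols(edges$from)
    edges$to <- canonicalizeSymbols(edges$to)
    ## store each pair in canonical (sorted) orientation
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges$from <- a
    edges$to <- b
  }
  edges <- edges[, c("from", "to", "confidence")]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(canonicalizeSymbols(nodes), edges$from, edges$to)))
  nodes <- nodes[nodes != ""]
  new("Network", nodes = nodes, edges = edges)
}

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "Network", function(x) x@nodes)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "Network", function(x) x@edges)

#' @rdname numNodes
#' @export
setMethod("numNodes", "Network", function(x) length(x@nodes))

#' @rdname numEdges
#' @export
setMethod("numEdges", "Network", function(x) nrow(x@edges))

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "Network", function(x) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(x@nodes), name = x@nodes)
  if (nrow(x@edges)) {
    idx <- rbind(match(x@edges$from, x@nodes), match(x@edges$to, x@nodes))
    g <- igraph::add_edges(g, as.vector(idx),
                           confidence = x@edges$confidence)
  }
  g
})

setMethod("show", "Network", function(object) {
  cat("Network with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges))
    cat("  confidence range: [",
        format(min(object@edges$confidence), digits = 3), ", ",
        format(max(object@edges$confidence), digits = 3), "]\n", sep = "")
})

## ---------------------------------------------------------------------------
## GeneSet
## ---------------------------------------------------------------------------

#' A named gene set
#'
#' One GMT-style gene set: pathway, GO/KEGG term, or any curated collection
#' used for over-representation testing and pathway labelling.
#'
#' @slot id Identifier (first GMT field).
#' @slot name Description (second GMT field).
#' @slot genes Character vector of unique canonical gene symbols, non-empty.
#' @export
setClass("GeneSet", representation(id = "character", name = "character",
                                   genes = "character"))

setValidity("GeneSet", function(object) {
  if (!length(object@genes)) return("gene set is empty")
  if (anyDuplicated(object@genes)) return("duplicate genes in set")
  TRUE
})

#' Construct a GeneSet
#'
#' @param id Term identifier.
#' @param name Human-readable description; defaults to `id`.
#' @param genes Character vector of gene symbols (canonicalized and
#'   deduplicated preserving first occurrence).
#' @return A [GeneSet-class] object.
#' @export
GeneSet <- function(id, genes, name = id) {
  genes <- unique(canonicalizeSymbols(genes))
  new("GeneSet", id = as.character(id), name = as.character(name),
      genes = genes)
}

#' @rdname members
#' @export
setMethod("members", "GeneSet", function(x) x@genes)

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet", object@id, "(", length(object@genes), "genes )\n")
})

## ---------------------------------------------------------------------------
## RWRResult
## ---------------------------------------------------------------------------

#' Random-walk-with-restart result
#'
#' Steady-state visiting probabilities of a restarting random walk seeded at
#' a gene set; the scores sum to one and quantify each node's proximity to
#' the seeds under network diffusion.
#'
#' @slot scores Named numeric vector over all network nodes; non-negative,
#'   summing to 1 (within 1e-9).
#' @slot seeds Character vector of seed genes.
#' @slot restart Restart probability used.
#' @slot iterations Number of power iterations to convergence.
#' @export
setClass("RWRResult", representation(scores = "numeric", seeds = "character",
                                     restart = "numeric",
                                     iterations = "integer"))

setValidity("RWRResult", function(object) {
  s <- object@scores
  if (is.null(names(s))) return("scores must be named")
  if (any(s < -1e-12)) return("negative score")
  if (abs(sum(s) - 1) > 1e-9) return("scores must sum to 1")
  TRUE
})

#' @rdname scores
#' @export
setMethod("scores", "RWRResult", function(x) x@scores)

setMethod("show", "RWRResult", function(object) {
  cat("RWRResult:", length(object@scores), "nodes,",
      length(object@seeds), "seeds, restart =", object@restart,
      "(", object@iterations, "iterations )\n")
  top <- utils::head(sort(object@scores, decreasing = TRUE), 5)
  cat("  top scores:",
      paste(names(top), format(top, digits = 3), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ProximityResult
## ---------------------------------------------------------------------------

#' Network proximity (separation) result
#'
#' Houses the separation index `s_AB = d_AB - (d_AA + d_BB)/2` between two
#' gene sets, built from closest-distance means over unweighted shortest
#' paths, together with an optional random-group null summary. Negative
#' `s_AB` indicates the two sets occupy overlapping network neighbourhoods.
#'
#' @slot s_ab Separation index.
#' @slot d_ab Mean closest distance between the sets.
#' @slot d_aa,d_bb Mean within-set closest distances.
#' @slot null_mean,null_sd Mean and standard deviation of `s_AB` across
#'   random control groups (`NA` when no null was computed).
#' @slot null_values Per-group null values (length `n_null`).
#' @slot n_null Number of random groups.
#' @slot seed Seed used for null sampling (`NA` when none).
#' @export
setClass("ProximityResult",
         representation(s_ab = "numeric", d_ab = "numeric", d_aa = "numeric",
                        d_bb = "numeric", null_mean = "numeric",
                        null_sd = "numeric", null_values = "numeric",
                        n_null = "integer", seed = "integer"))

setValidity("ProximityResult", function(object) {
  if (any(c(object@d_ab, object@d_aa, object@d_bb) < 0))
    return("distances must be non-negative")
  if (abs(object@s_ab - (object@d_ab - (object@d_aa + object@d_bb) / 2)) >
      1e-12)
    return("s_ab inconsistent with d_ab, d_aa, d_bb")
  TRUE
})

#' @rdname sAB
#' @export
setMethod("sAB", "ProximityResult", function(x) x@s_ab)

setMethod("show", "ProximityResult", function(object) {
  cat("ProximityResult: s_AB =", format(object@s_ab, digits = 4),
      "( d_AB =", format(object@d_ab, digits = 4),
      ", d_AA =", format(object@d_aa, digits = 4),
      ", d_BB =", format(object@d_bb, digits = 4), ")\n")
  if (object@n_null > 0)
    cat("  null over", object@n_null, "random groups: mean =",
        format(object@null_mean, digits = 4), ", sd =",
        format(object@null_sd, digits = 4), "\n")
})

## ---------------------------------------------------------------------------
## MCODEComplex
## ---------------------------------------------------------------------------

#' An MCODE complex
#'
#' A densely connected module found by the seeded vertex-weighting
#' algorithm; the score is the induced subgraph density multiplied by the
#' member count.
#'
#' @slot members Gene symbols in the complex (connected induced subgraph,
#'   at least two).
#' @slot score Density times member count.
#' @slot seed The seed gene the complex was grown from.
#' @export
setClass("MCODEComplex", representation(members = "character",
                                        score = "numeric",
                                        seed = "character"))

setValidity("MCODEComplex", function(object) {
  if (length(object@members) < 2) return("complex needs >= 2 members")
  if (object@score <= 0) return("score must be positive")
  TRUE
})

#' @rdname members
#' @export
setMethod("members", "MCODEComplex", function(x) x@members)

setMethod("show", "MCODEComplex", function(object) {
  cat("MCODEComplex ( seed", object@seed, "): score",
      format(object@score, digits = 4), ",", length(object@members),
      "members\n")
})
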