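## MCODE (Molecular Complex Detection): k-core based vertex weighting
## followed by greedy seed-and-grow complex prediction, with optional
## haircut and fluff post-processing. Defaults mirror the Cytoscape
## plugin's documented defaults.

.inducedDensity <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  igraph::ecount(g) / (n * (n - 1) / 2)
}

#' MCODE vertex weights
#'
#' For each node, the closed-neighbourhood subgraph is reduced to its
#' highest k-core; the weight is that core's density multiplied by its core
#' number k. Nodes with degree below `degreeCutoff` are weighted zero.
#'
#' @param network A [Network-class] object.
#' @param degreeCutoff Minimum degree for a node to receive a weight
#'   (default 2).
#' @return Named numeric vector of node weights.
#' @export
#' @examples
#' ## every vertex of an isolated K4 scores 3 (3-core of density 1)
#' k4 <- utils::combn(c("A", "B", "C", "D"), 2)
#' net <- Network(edges = data.frame(from = k4[1, ], to = k4[2, ],
#'                                   confidence = 1))
#' mcodeNodeScores(net)
mcodeNodeScores <- function(network, degreeCutoff = 2) {
  stopifnot(is(network, "Network"))
  g <- asIgraph(network)
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  for (v in which(deg >= degreeCutoff)) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k < 1) next
    coreSub <- igraph::induced_subgraph(sub, which(core >= k))
    w[v] <- .inducedDensity(coreSub) * k
  }
  w
}

#' Detect MCODE complexes
#'
#' Greedy seed-and-grow: the highest-weighted unassigned node seeds a
#' complex; neighbours are recruited (breadth-first, once each) while their
#' weight is at least `seed weight * (1 - nodeScoreCutoff)`. The haircut
#' step reduces each complex to its 2-core (removing singly connected
#' members); the optional fluff step adds unassigned boundary nodes whose
#' closed-neighbourhood density exceeds `fluffDensityCutoff`. Complexes
#' lacking a `kCore`-core are discarded. Every node belongs to at most one
#' complex. The complex score is the induced density multiplied by the
#' member count.
#'
#' @param network A [Network-class] object.
#' @param degreeCutoff,nodeScoreCutoff,kCore,haircut,fluff,fluffDensityCutoff
#'   Algorithm parameters (defaults 2, 0.2, 2, `TRUE`, `FALSE`, 0.2).
#' @return List of [MCODEComplex-class] objects, score descending (ties by
#'   seed symbol).
#' @export
mcodeFindComplexes <- function(network, degreeCutoff = 2,
                               nodeScoreCutoff = 0.2, kCore = 2,
                               haircut = TRUE, fluff = FALSE,
                               fluffDensityCutoff = 0.2) {
  stopifnot(is(network, "Network"))
  if (degreeCutoff < 2) stop("degreeCutoff must be >= 2")
  if (kCore < 2) stop("kCore must be >= 2")
  if (nodeScoreCutoff < 0 || nodeScoreCutoff > 1)
    stop("nodeScoreCutoff must lie in [0, 1]")
  g <- asIgraph(network)
  nodes <- igraph::V(g)$name
  w <- mcodeNodeScores(network, degreeCutoff)
  assigned <- stats::setNames(logical(length(nodes)), nodes)
  complexes <- list()

  repeat {
    cand <- names(w)[!assigned & w > 0]
    if (!length(cand)) break
    seed <- cand[order(-w[cand], cand)][1]
    threshold <- w[seed] * (1 - nodeScoreCutoff)

    ## breadth-first growth over unassigned nodes meeting the threshold
    membersL <- seed
    assigned[seed] <- TRUE
    queue <- seed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- names(igraph::neighbors(g, v))
      nb <- nb[!assigned[nb] & w[nb] >= threshold]
      if (length(nb)) {
        assigned[nb] <- TRUE
        membersL <- c(membersL, nb)
        queue <- c(queue, nb)
      }
    }
    if (length(membersL) < 2) next

    keep <- membersL
    if (haircut) {
      ## reduce to the 2-core of the complex subgraph
      sub <- igraph::induced_subgraph(g, keep)
      core <- igraph::coreness(sub)
      keep <- igraph::V(sub)$name[core >= 2]
      if (length(keep) < 2) next
    }
    if (fluff) {
      boundary <- setdiff(unique(unlist(lapply(
        igraph::adjacent_vertices(g, keep), names))), keep)
      boundary <- boundary[!assigned[boundary]]
      add <- boundary[vapply(boundary, function(b) {
        nb <- c(b, names(igraph::neighbors(g, b)))
        .inducedDensity(igraph::induced_subgraph(g, nb)) >
          fluffDensityCutoff
      }, FALSE)]
      if (length(add)) {
        assigned[add] <- TRUE
        keep <- c(keep, add)
      }
    }
    sub <- igraph::induced_subgraph(g, keep)
    if (max(igraph::coreness(sub)) < kCore) next
    score <- .inducedDensity(sub) * length(keep)
    complexes[[length(complexes) + 1L]] <-
      new("MCODEComplex", members = sort(keep), score = score, seed = seed)
  }

  if (!length(complexes)) return(list())
  ord <- order(-vapply(complexes, function(x) x@score, 0),
               vapply(complexes, function(x) x@seed, ""))
  complexes[ord]
}
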