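## Network proximity (separation) between two gene sets, in the
## closest-distance convention of Menche et al.: s_AB = d_AB -
## (d_AA + d_BB)/2 over unweighted shortest-path distances, plus a
## random-group null in which control sets of matched size are sampled
## uniformly from the network.

.setDistances <- function(network, from, to) {
  g <- asIgraph(network)
  igraph::distances(g, v = from, to = to, weights = NA)
}

.checkMembers <- function(network, genes, what) {
  missing <- setdiff(genes, networkNodes(network))
  if (length(missing))
    stop(what, " gene(s) not in network: ",
         paste(missing, collapse = ", "))
}

#' Mean closest distance between two gene sets
#'
#' `d_AB` averages, over every member of each set, the shortest-path
#' distance to the nearest member of the other set. A gene present in both
#' sets contributes distance zero.
#'
#' @param network A [Network-class] object.
#' @param setA,setB Non-empty character vectors of genes in the network.
#' @param onUnreachable `"error"` (default) to fail listing unreachable
#'   genes, or `"drop"` to discard them with a warning.
#' @return Non-negative numeric scalar.
#' @export
closestDistanceBetween <- function(network, setA, setB,
                                   onUnreachable = c("error", "drop")) {
  onUnreachable <- match.arg(onUnreachable)
  setA <- unique(canonicalizeSymbols(setA))
  setB <- unique(canonicalizeSymbols(setB))
  if (!length(setA) || !length(setB)) stop("gene sets must be non-empty")
  .checkMembers(network, setA, "set A")
  .checkMembers(network, setB, "set B")
  d <- .setDistances(network, setA, setB)
  minA <- apply(d, 1, min)   # nearest B for each a
  minB <- apply(d, 2, min)   # nearest A for each b
  vals <- c(minA, minB)
  if (any(is.infinite(vals))) {
    bad <- unique(c(setA[is.infinite(minA)], setB[is.infinite(minB)]))
    if (onUnreachable == "error")
      stop("unreachable gene(s): ", paste(bad, collapse = ", "))
    warning("dropping unreachable gene(s): ", paste(bad, collapse = ", "))
    vals <- vals[is.finite(vals)]
    if (!length(vals)) stop("no reachable pairs between the sets")
  }
  mean(vals)
}

#' Mean within-set closest distance
#'
#' `d_AA` averages, over each member, the shortest-path distance to its
#' nearest *other* member of the same set; undefined for singletons.
#'
#' @param network A [Network-class] object.
#' @param setA Character vector of at least two genes in the network.
#' @param onUnreachable `"error"` (default) or `"drop"`.
#' @return Non-negative numeric scalar.
#' @export
withinDistance <- function(network, setA,
                           onUnreachable = c("error", "drop")) {
  onUnreachable <- match.arg(onUnreachable)
  setA <- unique(canonicalizeSymbols(setA))
  if (length(setA) < 2)
    stop("within-set distance is undefined for fewer than 2 genes")
  .checkMembers(network, setA, "set A")
  d <- .setDistances(network, setA, setA)
  diag(d) <- Inf
  mins <- apply(d, 1, min)
  if (any(is.infinite(mins))) {
    bad <- setA[is.infinite(mins)]
    if (onUnreachable == "error")
      stop("unreachable gene(s): ", paste(bad, collapse = ", "))
    warning("dropping unreachable gene(s): ", paste(bad, collapse = ", "))
    mins <- mins[is.finite(mins)]
    if (!length(mins)) stop("no reachable within-set pairs")
  }
  mean(mins)
}

#' Network proximity index between two gene sets
#'
#' `s_AB = d_AB - (d_AA + d_BB) / 2`. Negative values indicate that the
#' two sets occupy the same network neighbourhood and hence suggest
#' related biological effects.
#'
#' @inheritParams closestDistanceBetween
#' @return A [ProximityResult-class] object (no null summary; see
#'   [nullControl()]).
#' @export
#' @examples
#' path <- Network(edges = data.frame(from = c("N1", "N2", "N3"),
#'                                    to = c("N2", "N3", "N4"),
#'                                    confidence = 1))
#' sAB(proximityIndex(path, c("N1", "N2"), c("N3", "N4")))  # 0.5
proximityIndex <- function(network, setA, setB,
                           onUnreachable = c("error", "drop")) {
  onUnreachable <- match.arg(onUnreachable)
  d_ab <- closestDistanceBetween(network, setA, setB, onUnreachable)
  d_aa <- withinDistance(network, setA, onUnreachable)
  d_bb <- withinDistance(network, setB, onUnreachable)
  new("ProximityResult", s_ab = d_ab - (d_aa + d_bb) / 2, d_ab = d_ab,
      d_aa = d_aa, d_bb = d_bb, null_mean = NA_real_, null_sd = NA_real_,
      null_values = numeric(), n_null = 0L, seed = NA_integer_)
}

#' Random-group null for the proximity index
#'
#' Samples `nGroups` gene groups of size `groupSize` uniformly without
#' replacement from the network nodes outside `setA`, computes each
#' group's proximity index to `setA`, and summarizes the null
#' distribution. Fully reproducible from `seed`.
#'
#' @param network A [Network-class] object.
#' @param setA Reference gene set (in the network).
#' @param groupSize Size of each random group (default `length(setA)`,
#'   matching the reference set as in separation-index controls).
#' @param nGroups Number of random groups (default 50).
#' @param seed Integer seed for the sampling.
#' @param onUnreachable Passed through to the distance computations;
#'   random groups on fragmented networks may need `"drop"`.
#' @return List with `null_mean`, `null_sd`, and `values` (per-group
#'   `s_AB`).
#' @export
nullControl <- function(network, setA, groupSize = length(setA),
                        nGroups = 50, seed = 1L,
                        onUnreachable = c("error", "drop")) {
  onUnreachable <- match.arg(onUnreachable)
  setA <- unique(canonicalizeSymbols(setA))
  if (groupSize < 2) stop("groupSize must be >= 2")
  .checkMembers(network, setA, "set A")
  eligible <- setdiff(networkNodes(network), setA)
  if (length(eligible) < groupSize)
    stop("too few eligible nodes to sample a group of size ", groupSize)
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(nGroups), function(i) {
    grp <- sample(eligible, groupSize)
    sAB(proximityIndex(network, setA, grp, onUnreachable))
  }, 0)
  list(null_mean = mean(vals), null_sd = stats::sd(vals), values = vals)
}

#' Proximity index with an attached random-group null
#'
#' Convenience wrapper combining [proximityIndex()] and [nullControl()]
#' into one [ProximityResult-class].
#'
#' @inheritParams proximityIndex
#' @inheritParams nullControl
#' @return A [ProximityResult-class] with the null summary filled in.
#' @export
proximityWithNull <- function(network, setA, setB, nGroups = 50,
                              seed = 1L,
                              onUnreachable = c("error", "drop")) {
  onUnreachable <- match.arg(onUnreachable)
  res <- proximityIndex(network, setA, setB, onUnreachable)
  null <- nullControl(network, setA,
                      groupSize = length(unique(canonicalizeSymbols(setB))),
                      nGroups = nGroups, seed = seed,
                      onUnreachable = onUnreachable)
  new("ProximityResult", s_ab = res@s_ab, d_ab = res@d_ab,
      d_aa = res@d_aa, d_bb = res@d_bb, null_mean = null$null_mean,
      null_sd = null$null_sd, null_values = null$values,
      n_null = as.integer(nGroups), seed = as.integer(seed))
}
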