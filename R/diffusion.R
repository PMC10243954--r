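## Random walk with restart: power iteration on the column-normalized
## adjacency with a restart vector uniform over the seed set.

#' Random walk with restart
#'
#' Iterates `p <- (1 - r) W p + r e` to its fixed point, where `W` is the
#' column-normalized adjacency matrix (unweighted by default) and `e` is
#' uniform over the seeds. Mass arriving at dangling (isolated) nodes is
#' redirected to the restart vector, so the scores always sum to one.
#' Iteration stops when the L1 change drops below `tol`.
#'
#' @param network A [Network-class] object with at least one edge.
#' @param seeds Non-empty character vector of seed genes, all present in
#'   the network.
#' @param restart Restart probability `r` in (0, 1\] (default 0.7, a
#'   common choice in gene-prioritization work).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param maxIter Iteration cap; non-convergence is an error.
#' @param weighted Use edge confidences as walk weights (default `FALSE`:
#'   the walk is unweighted and confidences only gate edge existence).
#' @return An [RWRResult-class] object.
#' @export
#' @examples
#' net <- Network(edges = data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                   confidence = 1))
#' res <- rwr(net, seeds = "A", restart = 0.5)
#' scores(res)  # (7/12, 1/3, 1/12)
rwr <- function(network, seeds, restart = 0.7, tol = 1e-10,
                maxIter = 1000L, weighted = FALSE) {
  stopifnot(is(network, "Network"))
  if (restart <= 0 || restart > 1) stop("restart must lie in (0, 1]")
  if (tol <= 0) stop("tol must be positive")
  if (numEdges(network) < 1) stop("network has no edges")
  seeds <- unique(canonicalizeSymbols(seeds))
  if (!length(seeds)) stop("seed set is empty")
  nodes <- networkNodes(network)
  missing <- setdiff(seeds, nodes)
  if (length(missing))
    stop("seed(s) not in network: ", paste(missing, collapse = ", "))

  n <- length(nodes)
  e <- stats::setNames(numeric(n), nodes)
  e[seeds] <- 1 / length(seeds)

  ed <- edgeTable(network)
  i <- match(ed$from, nodes); j <- match(ed$to, nodes)
  wt <- if (weighted) ed$confidence else rep(1, nrow(ed))
  A <- matrix(0, n, n)
  A[cbind(i, j)] <- wt
  A[cbind(j, i)] <- wt
  colsum <- colSums(A)
  dangling <- colsum == 0
  W <- A
  nz <- which(!dangling)
  W[, nz] <- sweep(A[, nz, drop = FALSE], 2, colsum[nz], "/")

  p <- e
  for (iter in seq_len(maxIter)) {
    pnew <- (1 - restart) * (as.vector(W %*% p) +
                               sum(p[dangling]) * e) + restart * e
    if (sum(abs(pnew - p)) < tol) {
      return(new("RWRResult", scores = stats::setNames(pnew, nodes),
                 seeds = seeds, restart = restart,
                 iterations = as.integer(iter)))
    }
    p <- pnew
  }
  stop("random walk did not converge in ", maxIter, " iterations")
}

#' Top diffusion candidates
#'
#' Ranks nodes by diffusion score (descending, ties broken by gene symbol
#' ascending) and returns the first `k`. Seeds are kept in the ranking by
#' default; set `includeSeeds = FALSE` to prioritise non-seed genes only.
#'
#' @param result An [RWRResult-class] object.
#' @param k Number of candidates (positive; capped at the node count).
#' @param includeSeeds Keep seed genes in the ranking (default `TRUE`).
#' @return `data.frame` with columns `gene`, `score`, `is_seed` in rank
#'   order.
#' @export
topCandidates <- function(result, k = 10, includeSeeds = TRUE) {
  stopifnot(is(result, "RWRResult"))
  if (k <= 0) stop("k must be positive")
  s <- scores(result)
  df <- data.frame(gene = names(s), score = unname(s),
                   is_seed = names(s) %in% result@seeds,
                   stringsAsFactors = FALSE)
  if (!includeSeeds) df <- df[!df$is_seed, , drop = FALSE]
  df <- df[order(-df$score, df$gene), , drop = FALSE]
  df <- utils::head(df, k)
  rownames(df) <- NULL
  df
}
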