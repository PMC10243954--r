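## Hypergeometric over-representation testing with Benjamini-Hochberg
## correction, plus correlation-based gene clustering.

#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked genes when `n` genes are drawn from a
#' universe of `N` containing `K` marked. Computed from the log-space
#' cumulative distribution for numerical stability.
#'
#' @param k Observed overlap (vectorized).
#' @param K Term size.
#' @param n Query size.
#' @param N Universe size.
#' @return Probability in (0, 1\].
#' @export
#' @examples
#' hypergeometricUpper(5, 5, 5, 10)  # 1 / choose(10, 5)
hypergeometricUpper <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k < 0) || any(k > pmin(K, n)))
    stop("k must lie in [0, min(K, n)]")
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                    log.p = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, order-preserving with the input.
#'
#' @param pvalues Numeric vector of probabilities.
#' @return Adjusted values, each in \[0, 1\].
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term for over-representation of the query within the
#' universe. The universe defaults to the union of all term genes; query
#' genes outside it are dropped with a warning and term genes are
#' intersected with it. Only terms overlapping the query (k >= 1) are
#' reported.
#'
#' @param query Character vector of query genes.
#' @param terms List of [GeneSet-class] objects.
#' @param universe Optional character vector of background genes.
#' @param pCutoff Raw-p significance flag threshold (default 0.005).
#' @return `data.frame` with columns `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p`, `p_adj`, `significant`, `overlap_genes`
#'   (semicolon-separated), sorted by `p` ascending (ties by term id).
#' @export
enrich <- function(query, terms, universe = NULL, pCutoff = 0.005) {
  query <- unique(canonicalizeSymbols(query))
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(terms, members)))
  } else {
    universe <- unique(canonicalizeSymbols(universe))
  }
  if (!length(universe)) stop("universe is empty")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(terms, function(t) {
    genes <- intersect(t@genes, universe)
    ov <- intersect(query, genes)
    if (!length(ov)) return(NULL)
    data.frame(term_id = t@id, term_name = t@name, k = length(ov),
               K = length(genes), n = n, N = N,
               p = hypergeometricUpper(length(ov), length(genes), n, N),
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, FALSE)]
  if (!length(rows)) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), p_adj = numeric(),
                      significant = logical(),
                      overlap_genes = character()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p)
  out$significant <- out$p < pCutoff
  out <- out[order(out$p, out$term_id),
             c("term_id", "term_name", "k", "K", "n", "N", "p", "p_adj",
               "significant", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Correlation-based gene clustering
#'
#' Average-linkage hierarchical clustering on the distance
#' `1 - correlation`, cut to `nClusters`. A transparent stand-in for
#' co-expression module services: the caller supplies the gene-gene
#' correlation matrix.
#'
#' @param matrix Symmetric correlation matrix with unit diagonal.
#' @param genes Character vector naming the rows/columns (defaults to the
#'   matrix dimnames).
#' @param nClusters Number of clusters to cut.
#' @return Named integer vector assigning each gene a cluster label.
#' @export
correlationClusters <- function(matrix, genes = rownames(matrix),
                                nClusters) {
  if (is.null(genes) || length(genes) != nrow(matrix))
    stop("genes must match the matrix dimension")
  if (nrow(matrix) != ncol(matrix) ||
      max(abs(matrix - t(matrix))) > 1e-9)
    stop("correlation matrix must be symmetric")
  if (nClusters < 1 || nClusters > nrow(matrix))
    stop("nClusters must lie in [1, number of genes]")
  d <- stats::as.dist(1 - matrix)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = nClusters)
  stats::setNames(as.integer(cl), genes)
}
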