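## Independent oracles, deliberately written from first principles (plain
## BFS / enumeration) so they share no code path with the package.

## adjacency list from a Network's edge table
adjList <- function(net) {
  nodes <- networkNodes(net)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  e <- edgeTable(net)
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  adj
}

## all-pairs unweighted shortest-path distances by queue-based BFS
bfsDistOracle <- function(net) {
  nodes <- networkNodes(net)
  adj <- adjList(net)
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

## exact unnormalized betweenness from BFS shortest-path counts
betweennessOracle <- function(net) {
  nodes <- networkNodes(net)
  d <- bfsDistOracle(net)
  ## sigma[s, t]: number of shortest s-t paths, by dynamic programming
  ## over BFS layers
  adj <- adjList(net)
  sigma <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  for (s in nodes) {
    sigma[s, s] <- 1
    ord <- nodes[order(d[s, ])]
    for (t in ord) {
      if (t == s || is.infinite(d[s, t])) next
      preds <- adj[[t]][d[s, adj[[t]]] == d[s, t] - 1]
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    tot <- 0
    for (s in nodes) {
      for (t in nodes) {
        if (s >= t || s == v || t == v) next
        if (is.infinite(d[s, t]) || sigma[s, t] == 0) next
        if (d[s, v] + d[v, t] == d[s, t])
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    bc[v] <- tot
  }
  bc
}

## exhaustive hypergeometric upper tail: enumerate all C(N, n) draws from
## a universe whose first K elements are marked
hyperUpperOracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

## random Erdos-Renyi network with gene-style names
randomNetwork <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  Network(nodes = nodes,
          edges = data.frame(from = pairs[1, keep], to = pairs[2, keep],
                             confidence = stats::runif(sum(keep), 0.5, 1)))
}

## a path graph A-B-C-... as a Network
pathNetwork <- function(labels) {
  n <- length(labels)
  Network(edges = data.frame(from = labels[-n], to = labels[-1],
                             confidence = 1))
}

## complete graph on the given labels
cliqueNetwork <- function(labels) {
  pairs <- utils::combn(labels, 2)
  Network(edges = data.frame(from = pairs[1, ], to = pairs[2, ],
                             confidence = 1))
}

## minimal compound row(s) for screen tests
compoundRow <- function(ob = 40, caco2 = 0.6, dl = 0.3, half_life = 5,
                        mw = 400, alogp = 3, h_donors = 2,
                        h_acceptors = 5) {
  data.frame(ob = ob, caco2 = caco2, dl = dl, half_life = half_life,
             mw = mw, alogp = alogp, h_donors = h_donors,
             h_acceptors = h_acceptors)
}
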