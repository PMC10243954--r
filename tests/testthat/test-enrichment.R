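test_that("hypergeometric upper tail matches closed forms", {
  expect_equal(hypergeometricUpper(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeometricUpper(0, 3, 4, 10), 1)
  expect_equal(hypergeometricUpper(6, 6, 6, 6), 1)
  expect_error(hypergeometricUpper(4, 3, 5, 10), "min\\(K, n\\)")
  expect_error(hypergeometricUpper(1, 11, 5, 10), "exceed N")
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  set.seed(55)
  for (i in 1:12) {
    N <- sample(6:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometricUpper(k, K, n, N),
                 hyperUpperOracle(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.05, 4)), rep(0.05, 4))
  expect_error(bhAdjust(c(0.1, 1.4)), "\\[0, 1\\]")
  ## monotone non-decreasing on sorted input
  set.seed(56)
  p <- sort(stats::runif(20))
  expect_true(all(diff(bhAdjust(p)) >= -1e-15))
  expect_true(all(bhAdjust(p) >= p))
})

test_that("enrich reports overlapping terms with consistent p-values", {
  universe <- sprintf("U%02d", 1:40)
  terms <- list(GeneSet("T1", universe[1:10]),
                GeneSet("T2", universe[11:20]),
                GeneSet("T3", universe[31:40]))
  query <- universe[c(1:6, 11)]
  res <- enrich(query, terms, universe = universe, pCutoff = 0.005)
  expect_equal(res$term_id[1], "T1")
  expect_false("T3" %in% res$term_id)  # disjoint from the query
  for (i in seq_len(nrow(res)))
    expect_equal(res$p[i],
                 hypergeometricUpper(res$k[i], res$K[i], res$n[i],
                                     res$N[i]))
  expect_true(all(res$p_adj >= res$p))

  ## p_cutoff = 1 flags everything reported
  res1 <- enrich(query, terms, universe = universe, pCutoff = 1)
  expect_true(all(res1$significant))

  expect_warning(enrich(c(query, "NOT_THERE"), terms,
                        universe = universe),
                 "outside the universe")
  expect_error(enrich(query, terms, universe = character()), "empty")
})

test_that("the planted enriched term ranks first on synthetic sets", {
  universe <- sprintf("G%04d", 1:200)
  hits <- 0
  for (s in 1:25) {
    cfg <- syntheticConfig(seed = 400 + s)
    set.seed(s); query <- sample(universe, 40)
    gs <- genGeneSets(cfg, query)
    res <- enrich(query, gs$sets, universe = universe)
    if (nrow(res) && res$term_id[1] == gs$planted) hits <- hits + 1
  }
  expect_gte(hits, 24)
})

test_that("correlation clustering recovers planted blocks", {
  cfg <- syntheticConfig(seed = 6, correlation_blocks = 2,
                         block_correlation = 0.8)
  genes <- sprintf("B%02d", 1:20)
  m <- genCorrelationMatrix(cfg, genes)
  cl <- correlationClusters(m, nClusters = 2)
  truth <- attr(m, "blocks")
  ## exact recovery up to label swapping
  agree <- max(mean((cl == 1) == (truth == 1)),
               mean((cl == 1) == (truth == 2)))
  expect_equal(agree, 1)

  ## k = number of genes means singleton clusters
  single <- correlationClusters(m, nClusters = 20)
  expect_equal(sort(unname(single)), 1:20)

  ## permuting gene order permutes the partition identically
  ## (compare co-membership, since cluster labels follow input order)
  perm <- sample(20)
  cl2 <- correlationClusters(m[perm, perm], nClusters = 2)
  expect_equal(outer(cl2, cl2, "=="),
               outer(cl[perm], cl[perm], "=="))

  bad <- m; bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(correlationClusters(bad, nClusters = 2), "symmetric")
})
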