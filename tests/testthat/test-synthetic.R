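test_that("generators are pure functions of the seed", {
  cfg <- syntheticConfig(seed = 42)
  expect_identical(genCompoundTable(cfg), genCompoundTable(cfg))
  expect_identical(genPPI(cfg), genPPI(cfg))
  expect_identical(genTargetAssociations(cfg), genTargetAssociations(cfg))
  expect_identical(genDiseaseGenes(cfg), genDiseaseGenes(cfg))
  expect_identical(genRegulationTable(cfg), genRegulationTable(cfg))
  expect_identical(genGeneSets(cfg, "G0001"), genGeneSets(cfg, "G0001"))
  ## different seeds give different fixtures
  expect_false(identical(genCompoundTable(cfg),
                         genCompoundTable(syntheticConfig(seed = 43))))
})

test_that("compound generator honours the pass fraction at its limits", {
  allPass <- genCompoundTable(syntheticConfig(seed = 3, n_compounds = 20,
                                              pass_fraction = 1))
  expect_true(all(passesScreen(allPass)))
  nonePass <- genCompoundTable(syntheticConfig(seed = 3, n_compounds = 20,
                                               pass_fraction = 0))
  expect_false(any(passesScreen(nonePass)))
  ## every compound belongs to at least one herb
  expect_true(all(nchar(allPass$herb_ids) > 0))
})

test_that("planted PPI structure matches its construction rules", {
  cfg <- syntheticConfig(seed = 11)
  ppi <- genPPI(cfg)
  g <- asIgraph(ppi$network)

  ## the planted clique induces all choose(k, 2) edges
  sub <- igraph::induced_subgraph(g, ppi$clique)
  expect_equal(igraph::ecount(sub), choose(length(ppi$clique), 2))

  ## B_near lies in the 1-hop neighbourhood of A; B_far at distance >= 3
  d <- igraph::distances(g, v = ppi$set_a, weights = NA)
  expect_true(all(apply(d[, ppi$set_b_near, drop = FALSE], 2, min) <= 1))
  expect_true(all(apply(d[, ppi$set_b_far, drop = FALSE], 2, min) >= 3))

  ## confidences survive a 0.4 filter
  expect_true(all(edgeTable(ppi$network)$confidence > 0.4))
})

test_that("preferential-attachment graphs are connected across seeds", {
  for (s in 1:100) {
    ppi <- genPPI(syntheticConfig(seed = s))
    comp <- igraph::components(asIgraph(ppi$network))
    expect_equal(comp$no, 1)
  }
})

test_that("correlation matrices have the planted block structure", {
  cfg <- syntheticConfig(seed = 5)
  genes <- sprintf("X%02d", 1:40)
  m <- genCorrelationMatrix(cfg, genes)
  expect_equal(unname(diag(m)), rep(1, 40))
  expect_equal(m, t(m))
  expect_true(all(m >= -1 & m <= 1))
  blocks <- attr(m, "blocks")
  within <- outer(blocks, blocks, "==") & upper.tri(m)
  expect_lt(abs(mean(m[within]) - cfg@block_correlation), 0.05)
  expect_lt(abs(mean(m[!within & upper.tri(m)])), 0.1)
  expect_error(genCorrelationMatrix(cfg, genes[1:3]), "fewer genes")
})

test_that("score and probability distributions have the stated shape", {
  cfg <- syntheticConfig(seed = 9, n_associations = 2000)
  dg <- genDiseaseGenes(cfg)
  expect_true(all(dg$score > 0))
  expect_true(all(dg$source %in% c("genecards", "disgenet")))
  expect_false(anyDuplicated(paste(dg$gene, dg$source)) > 0)

  ## association probabilities are Uniform(0, 1): about 20% exceed 0.8
  set.seed(901)
  p <- stats::runif(2000)  # what the generator draws before dedup
  assoc <- genTargetAssociations(syntheticConfig(seed = 9,
                                                 n_associations = 2000,
                                                 n_genes = 5000,
                                                 n_compounds = 500))
  expect_lt(abs(mean(assoc$probability > 0.8) - 0.2), 0.03)

  reg <- genRegulationTable(cfg)
  expect_true(all(reg$mode %in% c("activation", "repression", "unknown")))
  expect_true(all(reg$regulator != reg$target))
})

test_that("gene-set generator plants exactly one enriched term", {
  cfg <- syntheticConfig(seed = 13)
  query <- sprintf("G%04d", 1:30)
  gs <- genGeneSets(cfg, query)
  expect_length(gs$sets, cfg@n_terms)
  sizes <- vapply(gs$sets, function(s) length(members(s)), 0L)
  expect_true(all(sizes >= cfg@term_size_min &
                    sizes <= cfg@term_size_max))
  expect_true(gs$planted %in% vapply(gs$sets, function(s) s@id, ""))
  expect_error(genGeneSets(cfg, character()), "empty")

  ## planted overlap beats the uniform expectation on average
  overlapOf <- function(strength) {
    mean(vapply(1:30, function(s) {
      cfg <- syntheticConfig(seed = s, enrichment_strength = strength)
      gs <- genGeneSets(cfg, query)
      planted <- gs$sets[[match(gs$planted,
                                vapply(gs$sets, function(x) x@id, ""))]]
      length(intersect(members(planted), query)) /
        length(members(planted))
    }, 0))
  }
  expect_gt(overlapOf(8), overlapOf(1) + 0.2)
})

test_that("config validity catches impossible settings", {
  expect_error(syntheticConfig(clique_size = 2), "clique_size")
  expect_error(syntheticConfig(pass_fraction = 1.5), "pass_fraction")
  expect_error(syntheticConfig(n_genes = 20), "planted structure")
  expect_error(syntheticConfig(block_correlation = 1), "block_correlation")
})
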