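test_that("buildNetwork filters strictly and honours restriction", {
  edges <- data.frame(node_a = c("A", "A", "B"),
                      node_b = c("B", "C", "C"),
                      confidence = c(0.39, 0.40, 0.41))
  net <- buildNetwork(edges)
  expect_equal(numEdges(net), 1)
  expect_equal(edgeTable(net)$confidence, 0.41)

  restricted <- buildNetwork(edges, minConfidence = 0,
                             restrictTo = c("A", "B"))
  expect_equal(numEdges(restricted), 1)  # A-C and B-C dropped
  expect_equal(networkNodes(restricted), c("A", "B"))

  ## isolated permitted nodes are kept as degree-0 nodes
  iso <- buildNetwork(edges, minConfidence = 0,
                      restrictTo = c("A", "B", "Z"))
  expect_true("Z" %in% networkNodes(iso))

  all_kept <- buildNetwork(edges, minConfidence = 0)
  expect_equal(numEdges(all_kept), 3)
})

test_that("average degree and clustering match hand values", {
  two <- Network(edges = data.frame(from = "A", to = "B", confidence = 1))
  expect_equal(averageDegree(two), 1)
  tri <- cliqueNetwork(c("A", "B", "C"))
  expect_equal(averageDegree(tri), 2)
  expect_equal(averageClustering(tri), 1)
  expect_equal(averageClustering(pathNetwork(c("A", "B", "C"))), 0)

  ## K4 minus one edge: (1 + 1 + 2/3 + 2/3) / 4
  k4m <- Network(edges = data.frame(
    from = c("A", "A", "A", "B", "B"),
    to   = c("B", "C", "D", "C", "D"), confidence = 1))
  expect_equal(averageClustering(k4m), 5 / 6)
  expect_error(averageDegree(Network()), "empty")
})

test_that("centralities give exact degree and betweenness", {
  star <- Network(edges = data.frame(from = "HUB",
                                     to = c("L1", "L2", "L3"),
                                     confidence = 1))
  ct <- centralities(star)
  expect_equal(ct$betweenness[ct$node == "HUB"], 3)
  expect_equal(ct$betweenness[ct$node != "HUB"], rep(0, 3))

  path <- pathNetwork(c("A", "B", "C"))
  ct2 <- centralities(path)
  expect_equal(ct2$betweenness[ct2$node == "B"], 1)

  ## handshake lemma and the BFS path-counting oracle on random graphs
  for (s in 1:5) {
    net <- randomNetwork(n = 15 + 2 * s, p = 0.15, seed = 100 + s)
    ct <- centralities(net)
    expect_equal(sum(ct$degree), 2 * numEdges(net))
    oracle <- betweennessOracle(net)
    expect_equal(stats::setNames(ct$betweenness, ct$node),
                 oracle[ct$node], tolerance = 1e-9)
  }
})

test_that("the 2x-median key-target rule picks hubs only", {
  star <- Network(edges = data.frame(from = "HUB",
                                     to = c("L1", "L2", "L3"),
                                     confidence = 1))
  expect_equal(keyTargets(centralities(star)), "HUB")

  ## regular graphs have no node above twice the median
  ring <- Network(edges = data.frame(from = c("A", "B", "C", "D"),
                                     to = c("B", "C", "D", "A"),
                                     confidence = 1))
  expect_length(keyTargets(centralities(ring)), 0)

  ## invariance under node relabeling
  relabel <- Network(edges = data.frame(from = "ZHUB",
                                        to = c("A1", "A2", "A3"),
                                        confidence = 1))
  expect_equal(keyTargets(centralities(relabel)), "ZHUB")
})

test_that("compound degree ranking counts distinct common targets", {
  assocs <- data.frame(compound_id = c("c1", "c1", "c1", "c1", "c2"),
                       gene = c("A", "B", "C", "A", "Z"))
  aliases <- data.frame(compound_id = c("c1", "c2"),
                        label = c("A", "NX1"))
  rk <- compoundDegreeRanking(assocs, c("A", "B", "C", "D", "E"), aliases)
  expect_equal(rk$degree[rk$compound_id == "c1"], 3L)
  expect_equal(rk$degree[rk$compound_id == "c2"], 0L)
  expect_equal(rk$compound_id[nrow(rk)], "c2")
  ## permutation invariance of the association rows
  rk2 <- compoundDegreeRanking(assocs[sample(5), ],
                               c("A", "B", "C", "D", "E"), aliases)
  expect_equal(rk, rk2)
})

test_that("TF subnetworks keep in-set regulations and count out-degree", {
  reg <- data.frame(regulator = c("R1", "R1", "R2"),
                    target = c("T1", "T2", "T1"),
                    mode = c("activation", "repression", "unknown"))
  sub <- tfSubnetwork(reg, c("R1", "T1", "T2"))
  expect_equal(nrow(sub$edges), 2)  # R2 outside the gene set
  expect_equal(sub$outDegree[["R1"]], 2L)
  expect_error(tfSubnetwork(data.frame(regulator = "R", target = "T",
                                       mode = "boosts"), c("R", "T")),
               "unknown regulation mode")
})

test_that("betweenness of untouched nodes survives leaf removal", {
  ## removing a leaf not on any other shortest path leaves the rest alone
  net <- pathNetwork(c("A", "B", "C", "D"))
  withLeaf <- Network(edges = rbind(edgeTable(net),
                                    data.frame(from = "D", to = "E",
                                               confidence = 1)))
  ctFull <- centralities(withLeaf)
  ctSmall <- centralities(net)
  for (v in c("B", "C")) {
    ## B and C gain paths to E, so compare after dropping E's contribution
    expect_gte(ctFull$betweenness[ctFull$node == v],
               ctSmall$betweenness[ctSmall$node == v])
  }
})
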