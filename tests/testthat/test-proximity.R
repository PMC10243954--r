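p4 <- pathNetwork(c("N1", "N2", "N3", "N4"))

test_that("closest distances on the 4-path match hand computation", {
  expect_equal(closestDistanceBetween(p4, c("N1", "N2"), c("N3", "N4")),
               1.5)
  expect_equal(closestDistanceBetween(p4, "N1", "N4"), 3)
  ## overlapping sets contribute zero distances
  expect_equal(closestDistanceBetween(p4, c("N1", "N2"), c("N1", "N2")),
               0)
  expect_equal(withinDistance(p4, c("N1", "N2")), 1)
  expect_equal(withinDistance(cliqueNetwork(c("A", "B", "C", "D")),
                              c("A", "B", "C", "D")), 1)
  expect_error(withinDistance(p4, "N1"), "fewer than 2")
})

test_that("the separation index combines its parts and is symmetric", {
  res <- proximityIndex(p4, c("N1", "N2"), c("N3", "N4"))
  expect_equal(sAB(res), 0.5)
  expect_equal(res@d_ab, 1.5)
  expect_equal(res@d_aa, 1)
  expect_equal(res@d_bb, 1)

  ## identical sets give s = -d_AA <= 0
  same <- proximityIndex(p4, c("N1", "N2"), c("N1", "N2"))
  expect_equal(sAB(same), -1)

  rev <- proximityIndex(p4, c("N3", "N4"), c("N1", "N2"))
  expect_equal(sAB(rev), sAB(res))
})

test_that("distances agree with a BFS oracle on random graphs", {
  for (s in 1:5) {
    net <- randomNetwork(sample(10:30, 1), 0.25, seed = 800 + s)
    d <- bfsDistOracle(net)
    nodes <- networkNodes(net)
    ## restrict to the largest connected component
    comp <- igraph::components(asIgraph(net))
    big <- nodes[comp$membership == which.max(comp$csize)]
    if (length(big) < 5) next
    A <- sample(big, 2 + s %% 2)
    B <- sample(setdiff(big, A), 2)
    dAB_oracle <- (sum(apply(d[A, B, drop = FALSE], 1, min)) +
                     sum(apply(d[A, B, drop = FALSE], 2, min))) /
      (length(A) + length(B))
    expect_equal(closestDistanceBetween(net, A, B), dAB_oracle)
    dd <- d[A, A, drop = FALSE]; diag(dd) <- Inf
    expect_equal(withinDistance(net, A), mean(apply(dd, 1, min)))
  }
})

test_that("adding an edge never increases any distance component", {
  set.seed(77)
  for (s in 1:5) {
    net <- randomNetwork(12, 0.3, seed = 820 + s)
    comp <- igraph::components(asIgraph(net))
    nodes <- networkNodes(net)
    big <- nodes[comp$membership == which.max(comp$csize)]
    if (length(big) < 6) next
    A <- sample(big, 3); B <- sample(setdiff(big, A), 3)
    base <- proximityIndex(net, A, B)
    absent <- utils::combn(big, 2)
    et <- edgeTable(net)
    have <- paste(et$from, et$to)
    cand <- absent[, !(paste(pmin(absent[1, ], absent[2, ]),
                             pmax(absent[1, ], absent[2, ])) %in% have),
                   drop = FALSE]
    if (!ncol(cand)) next
    j <- sample(ncol(cand), 1)
    net2 <- Network(edges = rbind(et, data.frame(from = cand[1, j],
                                                 to = cand[2, j],
                                                 confidence = 1)))
    denser <- proximityIndex(net2, A, B)
    expect_lte(denser@d_ab, base@d_ab)
    expect_lte(denser@d_aa, base@d_aa)
    expect_lte(denser@d_bb, base@d_bb)
  }
})

test_that("unreachable members error by default or drop on request", {
  ## components {A, B, C} and {D, E}; D is unreachable from set A
  frag <- Network(edges = data.frame(from = c("A", "B", "D"),
                                     to = c("B", "C", "E"),
                                     confidence = 1))
  expect_error(closestDistanceBetween(frag, c("A", "B"), c("C", "D")),
               "unreachable")
  expect_warning(
    v <- closestDistanceBetween(frag, c("A", "B"), c("C", "D"),
                                onUnreachable = "drop"),
    "unreachable")
  expect_equal(v, mean(c(2, 1, 1)))  # A->C, B->C, C->B survive
  ## fully disconnected sets cannot be rescued by dropping
  expect_error(
    suppressWarnings(closestDistanceBetween(frag, c("A", "B"),
                                            c("D", "E"),
                                            onUnreachable = "drop")),
    "no reachable")
  expect_error(closestDistanceBetween(frag, "A", "Q"), "not in network")
})

test_that("the random-group null is reproducible and well-formed", {
  ppi <- genPPI(syntheticConfig(seed = 4))
  n1 <- nullControl(ppi$network, ppi$set_a, nGroups = 10, seed = 99)
  n2 <- nullControl(ppi$network, ppi$set_a, nGroups = 10, seed = 99)
  expect_identical(n1, n2)
  expect_length(n1$values, 10)
  expect_error(nullControl(ppi$network, ppi$set_a, groupSize = 1),
               "groupSize")

  full <- proximityWithNull(ppi$network, ppi$set_a, ppi$set_b_near,
                            nGroups = 10, seed = 99)
  expect_equal(full@n_null, 10L)
  expect_false(is.na(full@null_mean))
})

test_that("planted near sets separate from far sets and the null", {
  nearBelow <- 0; farAbove <- 0
  for (s in 1:25) {
    ppi <- genPPI(syntheticConfig(seed = 300 + s))
    sn <- sAB(proximityIndex(ppi$network, ppi$set_a, ppi$set_b_near))
    sf <- sAB(proximityIndex(ppi$network, ppi$set_a, ppi$set_b_far))
    null <- nullControl(ppi$network, ppi$set_a, nGroups = 20,
                        seed = 300 + s)
    if (sn < null$null_mean) nearBelow <- nearBelow + 1
    if (sf > sn) farAbove <- farAbove + 1
  }
  expect_gte(nearBelow, 24)
  expect_gte(farAbove, 24)
})
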