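test_that("loadEdgeList deduplicates, drops self-loops and reads SIF", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA"), tsv)
  g <- suppressMessages(loadEdgeList(tsv))
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("A", "B"))

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines("A\tpp\tB\tC", sif)
  g2 <- loadEdgeList(sif)
  expect_equal(igraph::ecount(g2), 2)
  expect_true(igraph::are_adjacent(g2, "A", "B"))
  expect_true(igraph::are_adjacent(g2, "A", "C"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_warning(g3 <- loadEdgeList(empty), "empty")
  expect_equal(igraph::vcount(g3), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Aonly", bad)
  expect_error(loadEdgeList(bad), "fewer than 2 fields")
})

test_that("induced signature subgraph discards unconnected members", {
  g <- edges_to_graph(cbind(c("A", "C"), c("B", "D")))
  sg <- inducedSignatureSubgraph(g, c("A", "B", "C"))
  expect_setequal(igraph::V(sg)$name, c("A", "B"))

  # signature members never adjacent to each other -> empty subgraph
  sg2 <- inducedSignatureSubgraph(g, c("A", "D"))
  expect_equal(igraph::vcount(sg2), 0)
})

test_that("a 548-feature signature with 157 unconnected members keeps 391", {
  # 391 signature nodes on a ring (each has a within-signature edge);
  # 157 further members connected only to non-signature partners
  ring <- paste0("R", 1:391)
  ringEdges <- cbind(ring, ring[c(2:391, 1)])
  lone <- paste0("U", 1:157)
  loneEdges <- cbind(lone, paste0("X", 1:157))
  g <- edges_to_graph(rbind(ringEdges, loneEdges))
  signature <- c(ring, lone)
  expect_equal(length(signature), 548)
  # independent degree scan on the raw edge list
  within <- rbind(ringEdges, loneEdges)
  within <- within[within[, 1] %in% signature & within[, 2] %in% signature, ]
  expect_equal(length(unique(c(within))), 391)
  sg <- inducedSignatureSubgraph(g, signature)
  expect_equal(igraph::vcount(sg), 391)
  expect_true(all(igraph::degree(sg) >= 1))
})

test_that("highestKCore matches brute-force pruning", {
  k5 <- t(combn(LETTERS[1:5], 2))
  hc <- highestKCore(edges_to_graph(k5))
  expect_equal(hc$k, 4)
  expect_setequal(hc$core, LETTERS[1:5])

  path <- cbind(c("A", "B"), c("B", "C"))
  expect_equal(highestKCore(edges_to_graph(path))$k, 1)

  k4p <- rbind(t(combn(LETTERS[1:4], 2)), c("A", "E"))
  got <- highestKCore(edges_to_graph(k4p))
  want <- oracle_highest_core(k4p, LETTERS[1:5])
  expect_equal(got$k, want$k)
  expect_identical(got$core, want$core)
  expect_equal(got$k, 3)

  expect_error(highestKCore(igraph::make_empty_graph(directed = FALSE)),
               "empty")
})

test_that("MCODE vertex weight agrees with the brute-force core oracle", {
  k5 <- t(combn(LETTERS[1:5], 2))
  expect_equal(unname(mcodeVertexWeight(edges_to_graph(k5), "A")), 4)

  star <- cbind("H", paste0("L", 1:4))
  expect_equal(unname(mcodeVertexWeight(edges_to_graph(star), "H")), 0.4)

  iso <- edges_to_graph(cbind("A", "B"), nodes = c("A", "B", "Z"))
  expect_equal(unname(mcodeVertexWeight(iso, "Z")), 0)
  expect_error(mcodeVertexWeight(iso, "missing"), "not in graph")

  # random graphs against the oracle
  withr::local_seed(7)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    nodes <- paste0("N", seq_len(n))
    pairs <- t(combn(nodes, 2))
    edges <- pairs[runif(nrow(pairs)) < 0.35, , drop = FALSE]
    g <- edges_to_graph(edges, nodes = nodes)
    w <- mcodeVertexWeight(g)
    for (v in nodes)
      expect_equal(unname(w[v]), oracle_vertex_weight(edges, nodes, v),
                   tolerance = 1e-12)
  }
})

test_that("vertex weight is invariant under node relabeling", {
  withr::local_seed(13)
  nodes <- paste0("N", 1:12)
  pairs <- t(combn(nodes, 2))
  edges <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
  w <- mcodeVertexWeight(edges_to_graph(edges, nodes))
  for (rep in 1:5) {
    perm <- setNames(sample(paste0("M", 1:12)), nodes)
    relEdges <- cbind(perm[edges[, 1]], perm[edges[, 2]])
    w2 <- mcodeVertexWeight(edges_to_graph(relEdges, unname(perm)))
    expect_equal(unname(w2[perm[nodes]]), unname(w[nodes]),
                 tolerance = 1e-12)
  }
})

test_that("mcodeComplexes recovers planted cliques and respects haircut", {
  withr::local_seed(3)
  k5a <- t(combn(paste0("A", 1:5), 2))
  k5b <- t(combn(paste0("B", 1:5), 2))
  bgNodes <- paste0("G", 1:20)
  bgPairs <- t(combn(bgNodes, 2))
  bg <- bgPairs[runif(nrow(bgPairs)) < 0.05, , drop = FALSE]
  bridges <- rbind(c("A1", "G1"), c("B1", "G2"))
  g <- edges_to_graph(rbind(k5a, k5b, bg, bridges),
                      nodes = c(paste0("A", 1:5), paste0("B", 1:5), bgNodes))
  cl <- mcodeComplexes(g, mcodeParams(vwp = 0.2))
  top2 <- cl$members[1:2]
  expect_setequal(top2[[1]], paste0("A", 1:5))
  expect_setequal(top2[[2]], paste0("B", 1:5))

  # edgeless graph: no clusters
  lonely <- edges_to_graph(matrix(character(), ncol = 2),
                           nodes = c("A", "B", "C"))
  expect_equal(nrow(mcodeComplexes(lonely)), 0)

  # a triangle is its own 2-core and survives haircut
  tri <- mcodeComplexes(edges_to_graph(t(combn(c("X", "Y", "Z"), 2))))
  expect_equal(nrow(tri), 1)
  expect_setequal(tri$members[[1]], c("X", "Y", "Z"))
})

test_that("clusters are disjoint and contained in their own 2-core", {
  withr::local_seed(17)
  for (s in 1:5) {
    sim <- simulatePlantedGraph(seed = s)
    cl <- mcodeComplexes(sim$graph)
    all_members <- unlist(cl$members)
    expect_equal(anyDuplicated(all_members), 0)
    for (m in cl$members) {
      sub <- igraph::induced_subgraph(sim$graph, m)
      if (length(m) >= 3)
        expect_gte(min(igraph::degree(sub)), 2)
    }
  }
})

test_that("buildMolecularModel records stage counts from planted truth", {
  sim <- simulatePlantedGraph(nBackground = 36, clusterSizes = c(8, 8, 8),
                              seed = 5)
  catalog <- igraph::V(sim$graph)$name   # 36 + 24 = 60 input features
  ann <- simulateAnnotations(catalog, nTerms = 30,
                             planted = list(PL1 = sim$clusters[[1]]),
                             seed = 5)
  model <- buildMolecularModel(sim$graph, catalog, ann)
  sc <- stageCounts(model)
  expect_equal(sc[["input_features"]], 60L)
  expect_equal(sc[["clusters"]], 3L)
  expect_equal(sc[["connected_features"]],
               sum(igraph::degree(sim$graph) > 0))
  expect_true(all(unlist(modelClusters(model)) %in%
                    igraph::V(modelSubgraph(model))$name))
  expect_identical(clusterMembers(model),
                   sort(unique(unlist(modelClusters(model)))))
  # scores sorted decreasing
  expect_false(is.unsorted(rev(clusterScores(model))))

  # catalog disjoint from network -> empty model
  expect_warning(
    empty <- buildMolecularModel(sim$graph, c("ZZ1", "ZZ2"), ann),
    "empty")
  expect_equal(unname(stageCounts(empty)[-1]), rep(0L, 4))
})
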