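pairsDf <- function(edges) {
  # edges: list of c(a, b, support, confidence, lift)
  data.frame(
    key = vapply(edges, function(e) paste(sort(e[1:2], method = "radix"),
                                          collapse = "+"), ""),
    support = vapply(edges, function(e) as.numeric(e[3]), 0),
    confidence = vapply(edges, function(e) as.numeric(e[4]), 0),
    lift = vapply(edges, function(e) as.numeric(e[5]), 0),
    stringsAsFactors = FALSE)
}

twoTriangles <- function() {
  prev <- c(A = 0.3, B = 0.25, C = 0.2, D = 0.3, E = 0.25, F = 0.2)
  pairs <- pairsDf(list(c("A", "B", .1, .4, 2), c("A", "C", .09, .4, 2),
                        c("B", "C", .08, .4, 2), c("D", "E", .1, .4, 2),
                        c("D", "F", .09, .4, 2), c("E", "F", .08, .4, 2)))
  buildNetwork(pairs, prev)
}

test_that("network construction counts nodes and edges correctly", {
  net <- twoTriangles()
  expect_identical(nrow(networkNodes(net)), 6L)
  expect_identical(nrow(networkEdges(net)), 6L)
  one <- buildNetwork(pairsDf(list(c("X", "Y", .05, .5, 2))),
                      c(X = .1, Y = .1))
  expect_identical(nrow(networkNodes(one)), 2L)
  expect_identical(nrow(networkEdges(one)), 1L)
})

test_that("duplicate pairs and missing prevalence are rejected", {
  dup <- pairsDf(list(c("A", "B", .1, .4, 2), c("B", "A", .1, .4, 2)))
  expect_error(buildNetwork(dup, c(A = .1, B = .1)), "duplicate")
  pairs <- pairsDf(list(c("A", "B", .1, .4, 2)))
  expect_error(buildNetwork(pairs, c(A = .1)), "'B'")
})

test_that("disconnected components become separate clusters", {
  net <- detectClusters(twoTriangles())
  lab <- clusterLabels(net)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(length(unique(lab[c("A", "B", "C")])), 1L)
  expect_identical(length(unique(lab[c("D", "E", "F")])), 1L)
  # cluster 1 is the higher-prevalence component; A-B-C wins on total 0.75
  expect_identical(unname(lab[["A"]]), 1L)
})

test_that("an isolated dyad forms its own cluster", {
  prev <- c(A = .3, B = .25, C = .2, X = .08, Y = .07)
  pairs <- pairsDf(list(c("A", "B", .1, .4, 2), c("A", "C", .09, .4, 2),
                        c("B", "C", .08, .4, 2), c("X", "Y", .05, .7, 9)))
  net <- detectClusters(buildNetwork(pairs, prev))
  lab <- clusterLabels(net)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(unname(lab[["X"]]), unname(lab[["Y"]]))
  expect_false(lab[["X"]] %in% lab[c("A", "B", "C")])
})

test_that("the partition's modularity beats the all-singletons partition", {
  set.seed(5)
  gen <- generateCohort(plantedCohortSpec(nPatients = 600L), seed = 5)
  tx <- asTransactions(filterCohort(gen$cohort)$cohort)
  rules <- deriveRules(mineFrequentItemsets(tx))
  net <- detectClusters(buildNetwork(topCombinations(rules, 2, 30),
                                     itemSupport(tx)))
  g <- igraph::graph_from_data_frame(networkEdges(net), directed = FALSE,
                                     vertices = networkNodes(net)$code)
  singletons <- seq_len(nrow(networkNodes(net)))
  qSingle <- igraph::modularity(g, singletons,
                                weights = networkEdges(net)$support)
  expect_gte(networkModularity(net), qSingle)
  # labels are a partition: one label per node
  expect_false(anyNA(clusterLabels(net)))
  # identical input, identical result
  net2 <- identifyCores(detectClusters(buildNetwork(
    topCombinations(rules, 2, 30), itemSupport(tx))))
  expect_identical(clusterLabels(net2), clusterLabels(identifyCores(net)))
  expect_identical(coreItems(net2), coreItems(identifyCores(net)))
})

test_that("core identification follows prevalence then weighted degree", {
  prev <- c(A = .3, B = .3, C = .2, D = .1)
  # A and B tie on prevalence; B has the higher support-weighted degree
  pairs <- pairsDf(list(c("A", "C", .05, .4, 2), c("B", "C", .10, .4, 2),
                        c("B", "D", .06, .4, 2), c("A", "D", .02, .4, 2)))
  net <- identifyCores(detectClusters(buildNetwork(pairs, prev)))
  expect_identical(coreItems(net)$global, "B")
  nd <- networkNodes(net)
  expect_true(nd$is_cluster_core[nd$code == "B"])
  # B is the core of whichever cluster holds it
  lab <- clusterLabels(net)
  expect_identical(coreItems(net)$perCluster[[as.character(lab[["B"]])]],
                   "B")
  expect_error(identifyCores(twoTriangles()), "detectClusters")
})

test_that("graphml and json exports round-trip the network", {
  net <- identifyCores(detectClusters(twoTriangles()))
  for (fmt in c("graphml", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    exportGraph(net, path, fmt)
    back <- importGraph(path, fmt)
    expect_identical(networkNodes(back)$code, networkNodes(net)$code)
    expect_identical(networkNodes(back)$cluster_id,
                     networkNodes(net)$cluster_id)
    expect_identical(networkNodes(back)$is_cluster_core,
                     networkNodes(net)$is_cluster_core)
    expect_equal(networkNodes(back)$prevalence,
                 networkNodes(net)$prevalence)
    expect_identical(networkEdges(back)$from, networkEdges(net)$from)
    expect_identical(networkEdges(back)$to, networkEdges(net)$to)
    for (at in c("support", "confidence", "lift"))
      expect_equal(networkEdges(back)[[at]], networkEdges(net)[[at]])
  }
  # unclustered networks export with the attribute absent
  raw <- twoTriangles()
  path <- tempfile(fileext = ".graphml")
  exportGraph(raw, path, "graphml")
  expect_false(grepl("cluster_id", paste(readLines(path), collapse = "")))
  # edge list keeps topology and weight; unknown formats error
  pe <- tempfile()
  exportGraph(net, pe, "edgelist")
  el <- read.table(pe)
  expect_identical(nrow(el), nrow(networkEdges(net)))
  expect_error(exportGraph(net, tempfile(), "dot"), "arg")
})

test_that("adjustedRand agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(3)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
})
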