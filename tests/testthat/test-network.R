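triangleEdges <- data.frame(Source = c("x", "x", "y"),
                            Target = c("y", "z", "z"))

test_that("buildGraph cleans the edge list and restricts to components", {
  e <- data.frame(Source = c("a", "b", "d"), Target = c("b", "c", "e"))
  g <- buildGraph(e, largestComponentOnly = TRUE)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))

  expect_equal(igraph::vcount(buildGraph(e[0, ])), 0)

  dup <- rbind(e, data.frame(Source = "b", Target = "a"))
  expect_warning(g2 <- buildGraph(dup), "duplicate")
  expect_equal(igraph::ecount(g2), 3)

  loop <- rbind(e, data.frame(Source = "a", Target = "a"))
  expect_warning(g3 <- buildGraph(loop), "self-loop")
  expect_equal(igraph::ecount(g3), 3)

  # component-size tie broken toward the lexicographically smallest member
  tie <- data.frame(Source = c("m", "a"), Target = c("n", "b"))
  g4 <- buildGraph(tie, largestComponentOnly = TRUE)
  expect_setequal(igraph::V(g4)$name, c("a", "b"))
})

test_that("coreness matches hand-peeled examples", {
  k4 <- edgesFromAdjacency(1 - diag(4))
  kc <- kcoreDecomposition(buildGraph(k4))
  expect_true(all(kc$coreness == 3))
  expect_identical(length(kc$coreNodes), 4L)

  path <- data.frame(Source = c("a", "b", "c", "d"),
                     Target = c("b", "c", "d", "e"))
  kcP <- kcoreDecomposition(buildGraph(path))
  expect_true(all(kcP$coreness == 1))
  expect_identical(length(kcP$coreNodes), 5L)

  triPend <- rbind(triangleEdges, data.frame(Source = "w", Target = "x"))
  kcT <- kcoreDecomposition(buildGraph(triPend))
  expect_identical(kcT$coreness[c("x", "y", "z", "w")],
                   c(x = 2L, y = 2L, z = 2L, w = 1L))
  expect_setequal(kcT$coreNodes, c("x", "y", "z"))
})

test_that("community detection separates cliques and keeps K6 whole", {
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1; adj[6:10, 6:10] <- 1; diag(adj) <- 0
  g <- buildGraph(edgesFromAdjacency(adj))
  truth <- rep(1:2, each = 5)
  names(truth) <- sprintf("n%02d", 1:10)
  for (method in c("louvain", "leiden")) for (seed in c(1, 99)) {
    res <- detectCommunities(g, method = method, seed = seed)
    memb <- res$membership[names(truth)]
    expect_identical(length(unique(memb)), 2L)
    expect_identical(length(unique(memb[1:5])), 1L)
    expect_identical(length(unique(memb[6:10])), 1L)
  }

  k6 <- buildGraph(edgesFromAdjacency(1 - diag(6)))
  expect_identical(length(unique(detectCommunities(k6)$membership)), 1L)

  expect_error(detectCommunities(g, method = "metis"),
               class = "slidenet_usage_error")
})

test_that("planted-partition blocks are recovered with high NMI", {
  set.seed(7)
  n <- 100
  truth <- rep(1:4, each = 25)
  p <- ifelse(outer(truth, truth, `==`), 0.3, 0.01)
  adj <- matrix(0, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- (runif(sum(ut)) < p[ut]) * 1
  adj <- adj + t(adj)
  g <- buildGraph(edgesFromAdjacency(adj))
  res <- detectCommunities(g, method = "leiden", seed = 42)
  names(truth) <- sprintf("n%02d", 1:n)
  nmi <- igraph::compare(res$membership[igraph::V(g)$name],
                         truth[igraph::V(g)$name], method = "nmi")
  expect_gte(nmi, 0.95)
})

test_that("community ids are 0-based, size-ordered, and modularity is exact", {
  set.seed(13)
  adj <- randomGraph(20, 0.2)
  g <- buildGraph(edgesFromAdjacency(adj))
  res <- detectCommunities(g, seed = 5)
  memb <- res$membership
  expect_identical(sort(unique(as.integer(memb))),
                   seq_len(length(unique(memb))) - 1L)
  sizes <- as.integer(table(memb))
  expect_true(all(diff(sizes) <= 0))                  # decreasing sizes
  expect_equal(length(memb), igraph::vcount(g))       # partition covers all

  ids <- as.integer(sub("n", "", igraph::V(g)$name))
  sub <- adj[ids, ids]
  expect_equal(res$modularity, directModularity(sub, memb), tolerance = 1e-9)

  res2 <- detectCommunities(g, seed = 5)
  expect_identical(res$membership, res2$membership)   # seed determinism
})

test_that("degree and strength follow the star examples", {
  star <- data.frame(Source = rep("hub", 4),
                     Target = paste0("leaf", 1:4), Weight = rep(0.9, 4))
  gU <- buildGraph(star)
  d <- degreeOrStrength(gU)
  expect_equal(d[["hub"]], 4)
  expect_true(all(d[paste0("leaf", 1:4)] == 1))

  gW <- buildGraph(star, useWeights = TRUE)
  expect_equal(degreeOrStrength(gW)[["hub"]], 3.6)

  gIso <- igraph::add_vertices(gU, 1, name = "alone")
  gIso <- igraph::set_graph_attr(gIso, "weighted", FALSE)
  expect_equal(degreeOrStrength(gIso)[["alone"]], 0)
})

test_that("eigenvector centrality matches closed forms and dense eigen", {
  k4 <- buildGraph(edgesFromAdjacency(1 - diag(4)))
  expect_equal(unname(eigenvectorCentrality(k4)), rep(0.5, 4),
               tolerance = 1e-8)

  star <- buildGraph(data.frame(Source = rep("hub", 3),
                                Target = paste0("leaf", 1:3)))
  ev <- eigenvectorCentrality(star)
  expect_equal(ev[["hub"]] / ev[["leaf1"]], sqrt(3), tolerance = 1e-6)

  two <- buildGraph(data.frame(Source = "a", Target = "b", Weight = 0.3),
                    useWeights = TRUE)
  expect_equal(unname(eigenvectorCentrality(two)), rep(1 / sqrt(2), 2),
               tolerance = 1e-8)

  set.seed(31)
  for (i in 1:5) {
    adj <- randomGraph(sample(10:50, 1), 0.15)
    g <- buildGraph(edgesFromAdjacency(adj))
    ids <- as.integer(sub("n", "", igraph::V(g)$name))
    want <- denseEigenvector(adj[ids, ids])
    expect_equal(unname(eigenvectorCentrality(g)), want, tolerance = 1e-6)
  }
})

test_that("betweenness and closeness match small enumerations", {
  path3 <- buildGraph(data.frame(Source = c("a", "b"), Target = c("b", "c")))
  bc <- betweennessCentrality(path3)
  expect_equal(bc[c("a", "b", "c")], c(a = 0, b = 1, c = 0))

  star <- buildGraph(data.frame(Source = rep("hub", 4),
                                Target = paste0("leaf", 1:4)))
  expect_equal(betweennessCentrality(star)[["hub"]], 6)  # 4*3/2 leaf pairs

  k4 <- buildGraph(edgesFromAdjacency(1 - diag(4)))
  expect_true(all(betweennessCentrality(k4) == 0))

  cc <- closenessCentrality(path3)
  expect_equal(cc[c("a", "b")], c(a = 1.5, b = 2))

  twoEdges <- buildGraph(data.frame(Source = c("a", "c"),
                                    Target = c("b", "d")))
  expect_true(all(closenessCentrality(twoEdges) == 1))

  expect_equal(closenessCentrality(star, "classic")[["hub"]], 1)
  expect_error(closenessCentrality(star, "euclid"),
               class = "slidenet_usage_error")
})

test_that("node property table composes all properties coherently", {
  g <- buildGraph(triangleEdges)
  res <- nodePropertyTable(g)
  expect_identical(nrow(res$table), 3L)
  expect_true(all(res$table$Coreness == 2))
  expect_true(all(res$table$IsCore))
  expect_identical(length(unique(res$table$Community)), 1L)
  expect_equal(res$summaries$coreness, data.frame(coreness = 2L, count = 3L))

  empty <- nodePropertyTable(buildGraph(triangleEdges[0, ]))
  expect_identical(nrow(empty$table), 0L)

  # coreness is topology-only: identical under weighted analysis
  we <- transform(triangleEdges, Weight = c(0.9, 0.8, 0.7))
  resW <- nodePropertyTable(buildGraph(we, useWeights = TRUE))
  expect_identical(resW$table$Coreness, res$table$Coreness)
  expect_false(isTRUE(all.equal(resW$table$Degree, res$table$Degree)))
})
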