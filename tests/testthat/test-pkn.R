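test_that("readNetwork parses edge lists, dedups, and validates signs", {
  path <- writeTempNetwork(data.frame(source = c("A", "B"),
                                      target = c("B", "C"),
                                      sign = c("activation", "inhibition")))
  net <- readNetwork(path)
  expect_s4_class(net, "SignedNetwork")
  expect_identical(nodeIds(net), c("A", "B", "C"))
  expect_equal(nrow(edgeTable(net)), 2)
  expect_equal(signMatrix(net)["B", "A"], 1)
  expect_equal(signMatrix(net)["C", "B"], -1)

  # duplicate consistent edge collapses to one
  path2 <- writeTempNetwork(data.frame(source = c("A", "A"),
                                       target = c("B", "B"),
                                       sign = c(1, 1)))
  expect_equal(nrow(edgeTable(readNetwork(path2))), 1)

  # conflicting duplicate names the pair
  path3 <- writeTempNetwork(data.frame(source = c("A", "A"),
                                       target = c("B", "B"),
                                       sign = c(1, -1)))
  expect_error(readNetwork(path3), "A -> B")

  # empty edge file and bad tokens
  path4 <- writeTempNetwork(data.frame(source = character(0),
                                       target = character(0),
                                       sign = numeric(0)))
  expect_error(readNetwork(path4), "no edges")
  path5 <- writeTempNetwork(data.frame(source = "A", target = "B",
                                       sign = "maybe"))
  expect_error(readNetwork(path5), "unmappable")
  path6 <- writeTempNetwork(data.frame(a = "A", b = "B", sign = 1))
  expect_error(readNetwork(path6), "missing columns")
})

test_that("network writing round-trips through the reader", {
  net <- tinyNetwork()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(net, path)
  net2 <- readNetwork(path)
  expect_identical(nodeIds(net2), nodeIds(net))
  expect_equal(adjacencyMatrix(net2), adjacencyMatrix(net))
  expect_equal(signMatrix(net2), signMatrix(net))
})

test_that("pruneReachable keeps the directed-reachability closure", {
  edges <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      sign = c(1, 1))
  net <- signedNetwork(edges, nodes = c("A", "B", "C", "D"))
  pruned <- pruneReachable(net, "A")
  expect_identical(nodeIds(pruned), c("A", "B", "C"))
  expect_equal(nrow(edgeTable(pruned)), 2)

  # source with no out-edges -> singleton network
  solo <- pruneReachable(net, "C")
  expect_identical(nodeIds(solo), "C")
  expect_equal(nrow(edgeTable(solo)), 0)

  expect_error(pruneReachable(net, "Z"), "unknown source")
})

test_that("pruneReachable matches a brute-force BFS oracle and is idempotent", {
  set.seed(11)
  nodes <- sprintf("n%02d", 1:50)
  edges <- unique(data.frame(
    source = sample(nodes, 120, replace = TRUE),
    target = sample(nodes, 120, replace = TRUE)))
  edges <- edges[edges$source != edges$target, ]
  edges$sign <- sample(c(-1, 1), nrow(edges), replace = TRUE)
  net <- signedNetwork(edges, nodes = nodes)
  for (src in c("n01", "n17", "n42")) {
    pruned <- pruneReachable(net, src)
    expect_setequal(nodeIds(pruned), bfsReachable(edges, src))
    # idempotent and a subgraph of the input
    again <- pruneReachable(pruned, src)
    expect_identical(nodeIds(again), nodeIds(pruned))
    expect_true(all(nodeIds(pruned) %in% nodeIds(net)))
    ep <- edgeTable(pruned)
    expect_true(all(paste(ep$source, ep$target) %in%
                      paste(edges$source, edges$target)))
  }
})

test_that("pruneByWeight keeps the boundary and composes by max threshold", {
  edges <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                      sign = c(1, -1, 1))
  net <- signedNetwork(edges)
  W <- matrix(0, 3, 3, dimnames = list(nodeIds(net), nodeIds(net)))
  W["B", "A"] <- 0.05; W["C", "B"] <- -0.2; W["A", "C"] <- 0.1
  tnet <- new("TrainedNetwork", network = net, weights = W,
              maskActive = TRUE)
  pruned <- pruneByWeight(tnet, 0.1)
  expect_equal(sum(weightMatrix(pruned) != 0), 2)   # boundary 0.1 kept
  expect_equal(weightMatrix(pruned)["C", "B"], -0.2)
  expect_equal(weightMatrix(pruned)["A", "C"], 0.1)

  expect_equal(weightMatrix(pruneByWeight(tnet, 0)), W)       # identity
  expect_equal(sum(weightMatrix(pruneByWeight(tnet, 10)) != 0), 0)
  expect_error(pruneByWeight(tnet, -1), "nonnegative")

  # prune(t2) o prune(t1) == prune(max(t1, t2))
  ab <- pruneByWeight(pruneByWeight(tnet, 0.08), 0.15)
  ba <- pruneByWeight(tnet, 0.15)
  expect_equal(weightMatrix(ab), weightMatrix(ba))
})

test_that("shortestSignalingDistance counts directed hops", {
  edges <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      sign = c(1, 1))
  net <- signedNetwork(edges)
  expect_equal(shortestSignalingDistance(net, "A", "C"), 2)
  expect_equal(shortestSignalingDistance(net, "A", "A"), 0)
  expect_identical(shortestSignalingDistance(net, "C", "A"), Inf)
  expect_error(shortestSignalingDistance(net, "A", "Z"), "unknown node")
})

test_that("shortestSignalingDistance agrees with path enumeration", {
  set.seed(5)
  nodes <- sprintf("m%02d", 1:30)
  edges <- unique(data.frame(
    source = sample(nodes, 70, replace = TRUE),
    target = sample(nodes, 70, replace = TRUE)))
  edges <- edges[edges$source != edges$target, ]
  edges$sign <- 1
  net <- signedNetwork(edges, nodes = nodes)
  adj <- adjacencyMatrix(net)
  pairs <- cbind(sample(nodes, 25, replace = TRUE),
                 sample(nodes, 25, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    d <- shortestSignalingDistance(net, pairs[i, 1], pairs[i, 2])
    oracle <- bruteShortestPath(adj, pairs[i, 1], pairs[i, 2], maxLen = 6)
    if (is.finite(oracle)) expect_equal(d, oracle)
    else expect_true(d > 6)   # oracle only enumerates up to length 6
  }
})

test_that("spectralRadius power iteration approaches the eigen oracle", {
  expect_equal(spectralRadius(diag(4)), 1.0)
  expect_equal(spectralRadius(diag(c(0.2, -0.9)), nIter = 60), 0.9,
               tolerance = 1e-6)
  expect_error(spectralRadius(matrix(1, 2, 3)), "square")

  set.seed(3)
  for (i in 1:5) {
    W <- matrix(rnorm(64), 8, 8)
    oracle <- max(Mod(eigen(W, only.values = TRUE)$values))
    expect_equal(spectralRadius(W, nIter = 50), oracle,
                 tolerance = 0.05 * oracle)
  }

  # estimates sharpen monotonically toward the oracle on symmetric matrices
  S <- crossprod(matrix(rnorm(36), 6, 6))
  oracle <- max(eigen(S, only.values = TRUE)$values)
  errs <- sapply(c(1, 3, 10, 30), function(k)
    abs(spectralRadius(S, k) - oracle))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("networkSummary reports counts, sign balance and self-loops", {
  edges <- rbind(tinyEdges(),
                 data.frame(source = "D", target = "D", sign = -1))
  net <- signedNetwork(edges)
  s <- networkSummary(net)
  expect_equal(s$nodes, 4)
  expect_equal(s$edges, 5)
  expect_equal(s$activating, 3)
  expect_equal(s$inhibiting, 2)
  expect_equal(s$self_loops, 1)
  path <- withr::local_tempfile(fileext = ".json")
  networkSummary(net, path)
  expect_equal(jsonlite::read_json(path)$nodes, 4)
})
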