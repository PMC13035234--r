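# Shared fixture builders: small networks, ground truths and datasets
# generated in code under fixed seeds.

tinyEdges <- function() {
  data.frame(source = c("A", "B", "B", "C"),
             target = c("B", "C", "D", "A"),
             sign = c(1, 1, -1, 1), stringsAsFactors = FALSE)
}

tinyNetwork <- function() signedNetwork(tinyEdges())

smallGroundTruth <- function(nNodes = 20, seed = 7, noiseSd = 0.05, ...) {
  net <- randomSignedNetwork(nNodes, avgDegree = 2.5, seed = seed)
  gt <- sampleGroundTruth(net, noiseSd = noiseSd, seed = seed + 1, ...)
  assignSites(gt, seed = seed + 2)
}

smallDataset <- function(gt = smallGroundTruth(), nDrugs = 2, ...) {
  generateTimecourse(gt, drugs = utils::head(names(gt@drugTargets), nDrugs),
                     ...)
}

# hand-rolled breadth-first search closure, independent of igraph
bfsReachable <- function(edges, source) {
  frontier <- source
  seen <- source
  repeat {
    nxt <- unique(edges$target[edges$source %in% frontier])
    nxt <- setdiff(nxt, seen)
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# brute-force shortest directed path by adjacency-matrix powers
bruteShortestPath <- function(adj, from, to, maxLen = 6) {
  if (from == to) return(0)
  P <- adj
  for (k in seq_len(maxLen)) {
    if (P[to, from] > 0) return(k)
    P <- P %*% adj
  }
  Inf
}

writeTempNetwork <- function(edges, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
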