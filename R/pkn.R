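#' Construct a signed directed network from an edge table
#'
#' Nodes are ordered by sorted identifier (deterministic across reads);
#' duplicate edges are collapsed and duplicates with conflicting signs are
#' rejected. Identifiers are matched case-preserving and exactly; no
#' gene-symbol aliasing is attempted. Self-loops are permitted (autoregulation
#' occurs in curated networks) and are reported by [networkSummary()].
#'
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (sign numeric in \{-1, +1\}).
#' @param nodes optional character vector of node ids to include (isolated
#'   nodes allowed); defaults to the union of edge endpoints.
#' @return a [SignedNetwork-class].
#' @export
signedNetwork <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "sign") %in% names(edges)))
  if (nrow(edges) == 0) stop("no edges")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.numeric(edges$sign)
  if (!all(edges$sign %in% c(-1, 1))) stop("edge signs must be -1 or +1")
  key <- paste(edges$source, edges$target, sep = "\r")
  nSigns <- tapply(edges$sign, key, function(s) length(unique(s)))
  if (any(nSigns > 1)) {
    bad <- names(nSigns)[nSigns > 1][1]
    pair <- strsplit(bad, "\r", fixed = TRUE)[[1]]
    stop("conflicting duplicate edge with opposite signs: ",
         pair[1], " -> ", pair[2])
  }
  edges <- edges[!duplicated(key), c("source", "target", "sign")]
  if (is.null(nodes)) nodes <- union(edges$source, edges$target)
  nodes <- sort(unique(as.character(nodes)))
  if (!all(c(edges$source, edges$target) %in% nodes))
    stop("edge endpoints missing from the supplied node set")
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  S <- A
  ti <- match(edges$target, nodes)
  si <- match(edges$source, nodes)
  A[cbind(ti, si)] <- 1
  S[cbind(ti, si)] <- edges$sign
  rownames(edges) <- NULL
  methods::new("SignedNetwork", nodes = nodes, edges = edges,
               adjacency = A, signs = S)
}

.SIGN_TOKENS <- c("1" = 1, "+1" = 1, "+" = 1, "activation" = 1,
                  "stimulation" = 1, "-1" = -1, "-" = -1,
                  "inhibition" = -1)

#' Read a signed directed network from a TSV edge list
#'
#' Reads an OmniPath-style edge list. Sign tokens `1`, `+1`, `+`,
#' `activation`, `stimulation` map to +1 and `-1`, `-`, `inhibition` to -1
#' (case-insensitive). See [signedNetwork()] for the dedup/ordering contract.
#'
#' @param path TSV file with at least source/target/sign columns.
#' @param dialect named character vector mapping the roles `source`, `target`,
#'   `sign` to the file's column names.
#' @return a [SignedNetwork-class].
#' @export
readNetwork <- function(path,
                        dialect = c(source = "source", target = "target",
                                    sign = "sign")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(dialect[c("source", "target", "sign")]), names(tab))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) stop("no edges")
  tok <- tolower(trimws(as.character(tab[[dialect[["sign"]]]])))
  sgn <- .SIGN_TOKENS[tok]
  if (anyNA(sgn))
    stop("unmappable sign token(s): ",
         paste(unique(tok[is.na(sgn)]), collapse = ", "))
  signedNetwork(data.frame(source = tab[[dialect[["source"]]]],
                           target = tab[[dialect[["target"]]]],
                           sign = unname(sgn), stringsAsFactors = FALSE))
}

#' Write a network edge list as TSV
#'
#' @param network a [SignedNetwork-class].
#' @param path output file.
#' @export
writeNetwork <- function(network, path) {
  utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.igraphOf <- function(network) {
  igraph::graph_from_data_frame(network@edges[, c("source", "target")],
                                directed = TRUE,
                                vertices = network@nodes)
}

#' Prune a network to the nodes reachable from a source
#'
#' Keeps the source plus every node reachable from it by a directed path and
#' the induced edges between retained nodes (used to restrict modeling to the
#' signaling cone downstream of the stimulated receptor). Node order is
#' preserved; the operation is idempotent.
#'
#' @param network a [SignedNetwork-class].
#' @param source node identifier (e.g. the stimulated receptor).
#' @return the induced reachable [SignedNetwork-class].
#' @export
pruneReachable <- function(network, source) {
  if (!source %in% network@nodes) stop("unknown source node: ", source)
  g <- .igraphOf(network)
  keep <- names(igraph::subcomponent(g, source, mode = "out"))
  keep <- network@nodes[network@nodes %in% keep]  # preserve order
  ed <- network@edges
  ed <- ed[ed$source %in% keep & ed$target %in% keep, , drop = FALSE]
  if (nrow(ed) == 0) {
    # singleton (or edgeless) reachable set
    n <- length(keep)
    A <- matrix(0, n, n, dimnames = list(keep, keep))
    return(methods::new("SignedNetwork", nodes = keep,
                        edges = ed, adjacency = A, signs = A))
  }
  signedNetwork(ed, nodes = keep)
}

#' Prune trained edges by weight magnitude
#'
#' Removes edges whose trained weight magnitude is strictly below the
#' threshold; edges with `|W| >= threshold` are kept (the boundary is kept).
#' The default 0.1 mirrors the pruning used when tracing signal-propagation
#' paths through a trained network.
#'
#' @param tnet a [TrainedNetwork-class].
#' @param threshold nonnegative magnitude cutoff.
#' @return a [TrainedNetwork-class] with the reduced support.
#' @export
pruneByWeight <- function(tnet, threshold = 0.1) {
  stopifnot(methods::is(tnet, "TrainedNetwork"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("threshold must be a single nonnegative number")
  keep <- abs(tnet@weights) >= threshold
  W <- tnet@weights * keep
  net <- tnet@network
  ed <- net@edges
  if (nrow(ed)) {
    wEdge <- W[cbind(match(ed$target, net@nodes), match(ed$source, net@nodes))]
    ed <- ed[wEdge != 0, , drop = FALSE]
  }
  A <- (W != 0) * 1
  S <- net@signs * A  # curated mode of action on surviving edges
  newNet <- methods::new("SignedNetwork", nodes = net@nodes, edges = ed,
                         adjacency = A, signs = S)
  methods::new("TrainedNetwork", network = newNet, weights = W,
               maskActive = tnet@maskActive)
}

#' Shortest signaling distance between two nodes
#'
#' Minimum number of directed edges on any path `from -> to`; `Inf` is the
#' "unreachable" sentinel. Used to map potential signal-propagation routes
#' from a drug target to a node of interest in a (weight-pruned) network.
#'
#' @param network a [SignedNetwork-class].
#' @param from,to node identifiers.
#' @return nonnegative integer hop count, or `Inf` when unreachable.
#' @export
shortestSignalingDistance <- function(network, from, to) {
  for (v in c(from, to))
    if (!v %in% network@nodes) stop("unknown node: ", v)
  if (from == to) return(0)
  g <- .igraphOf(network)
  d <- igraph::distances(g, v = from, to = to, mode = "out")[1, 1]
  if (is.infinite(d)) Inf else as.numeric(d)
}

#' Spectral radius estimate by power iteration
#'
#' Estimates the dominant eigenvalue magnitude of a square matrix with a
#' fixed number of power iterations started from the normalized all-ones
#' vector (no random restarts, so estimates are reproducible). The reported
#' value is the geometric mean of the per-step norm growth over the later
#' iterations, which also averages out the oscillation a complex dominant
#' eigenpair induces. This estimate is the one used inside the training
#' objective to promote convergent recurrent dynamics; five iterations per
#' update is the training default.
#'
#' @param W square numeric matrix.
#' @param nIter number of power iterations (>= 1).
#' @return nonnegative scalar estimate of the spectral radius.
#' @export
spectralRadius <- function(W, nIter = 5) {
  .spectralRadiusGrad(W, nIter)$value
}

# power iteration returning the estimate and its (stopped-vector) gradient.
# The estimate is the geometric mean of the per-step norm growth factors
# over the second half of the iterations: for a real dominant eigenvalue
# the growth factor settles and the mean is exact; for a complex dominant
# pair the single-step growth oscillates around the radius and the
# geometric mean averages the oscillation out. The gradient treats the
# final iterated vector as constant, d rho / dW ~ (W v) v^T / ||W v||.
.spectralRadiusGrad <- function(W, nIter = 5) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be a square matrix")
  stopifnot(nIter >= 1)
  n <- nrow(W)
  if (n == 0) return(list(value = 0, grad = W))
  v <- rep(1 / sqrt(n), n)
  logG <- numeric(nIter)
  for (k in seq_len(nIter)) {
    u <- drop(W %*% v)
    g <- sqrt(sum(u^2))
    if (g < .Machine$double.eps) return(list(value = 0, grad = 0 * W))
    logG[k] <- log(g)
    v <- u / g
  }
  keep <- seq.int(max(1, floor(nIter / 2) + 1), nIter)
  rho <- exp(mean(logG[keep]))
  u <- drop(W %*% v)
  nu <- sqrt(sum(u^2))
  grad <- if (nu > 0) tcrossprod(u, v) / nu else 0 * W
  list(value = rho, grad = grad)
}

#' Summarize a network
#'
#' @param network a [SignedNetwork-class].
#' @param path optional file; when given the summary is also written as JSON.
#' @return (invisibly) a list with node/edge counts, sign balance and
#'   self-loop count.
#' @export
networkSummary <- function(network, path = NULL) {
  ed <- network@edges
  out <- list(nodes = length(network@nodes), edges = nrow(ed),
              activating = sum(ed$sign == 1),
              inhibiting = sum(ed$sign == -1),
              self_loops = if (nrow(ed)) sum(ed$source == ed$target) else 0L)
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
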