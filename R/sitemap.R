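#' Gather node activities onto phosphosites
#'
#' Applies the binary selection matrix of a site assignment: each site's raw
#' input is exactly the trajectory of its single assigned node (a pure
#' gather, no mixing across nodes), so a site's prediction can only depend on
#' its own node's activity.
#'
#' @param states numeric array with nodes in the first dimension (e.g.
#'   nodes x samples x steps from [simulateTrajectory()], or a nodes x steps
#'   matrix) with node ids as rownames, or dimension matching `network`.
#' @param assignment a [SiteAssignment-class].
#' @param network a [SignedNetwork-class] defining the node order of
#'   `states`.
#' @return array with the node dimension replaced by one entry per site.
#' @export
mapNodesToSites <- function(states, assignment, network) {
  idx <- match(assignment@siteNodes, network@nodes)
  if (anyNA(idx)) stop("assignment refers to nodes absent from the network")
  d <- dim(states)
  if (is.null(d)) stop("states must be a matrix or array with nodes first")
  if (d[1] != length(network@nodes))
    stop("node dimension of states (", d[1], ") does not match the network")
  if (length(d) == 2) out <- states[idx, , drop = FALSE]
  else {
    flat <- matrix(states, nrow = d[1])
    out <- array(flat[idx, , drop = FALSE], c(length(idx), d[-1]))
  }
  out
}

#' Scale per-site embeddings by raw site inputs
#'
#' Each site's scalar raw input multiplies that site's trainable embedding
#' vector, giving a d-dimensional representation per site (and per
#' time/sample entry). Linear in the input: `embedSites(2h, E) = 2 embedSites(h, E)`.
#'
#' @param hSite sites x T matrix (or vector of one value per site) of raw
#'   site inputs.
#' @param E sites x d embedding matrix.
#' @return array sites x T x d (sites x d for vector input).
#' @export
embedSites <- function(hSite, E) {
  if (is.vector(hSite)) {
    if (length(hSite) != nrow(E)) stop("dimension mismatch")
    return(hSite * E)
  }
  if (nrow(hSite) != nrow(E)) stop("dimension mismatch")
  S <- outer(hSite, rep(1, ncol(E))) *
    aperm(array(E, c(nrow(E), ncol(E), ncol(hSite))), c(1, 3, 2))
  S
}

#' Create a shared site MLP
#'
#' One hidden layer with tanh nonlinearity and a linear scalar output,
#' shared across all phosphosites. One hidden layer is sufficient to recover
#' smooth node-to-site relations (cosine, polynomial, sigmoid, square root);
#' the width is configurable.
#'
#' @param d input width (embedding dimension, default 5).
#' @param hidden hidden-layer width (default 16).
#' @param seed RNG seed for the small random initialization.
#' @return list with elements `W1` (d x hidden), `b1`, `w2` (hidden), `b2`.
#' @export
makeSiteMLP <- function(d = 5, hidden = 16, seed = 1) {
  op <- .withSeed(seed)
  on.exit(op())
  list(W1 = matrix(stats::rnorm(d * hidden, sd = 1 / sqrt(d)), d, hidden),
       b1 = rep(0, hidden),
       w2 = stats::rnorm(hidden, sd = 1 / sqrt(hidden)),
       b2 = 0)
}

#' Collapse scaled embeddings to scalar site intensities
#'
#' Applies the shared MLP to each site's d-vector independently:
#' `yhat = w2' tanh(W1' s + b1) + b2`.
#'
#' @param S array sites x T x d (or sites x d matrix) of scaled embeddings,
#'   see [embedSites()].
#' @param mlp a shared MLP from [makeSiteMLP()].
#' @return sites x T matrix (vector for matrix input) of intensities.
#' @export
siteIntensity <- function(S, mlp) {
  d <- dim(S)
  dIn <- d[length(d)]
  if (dIn != nrow(mlp$W1)) stop("embedding width does not match MLP input")
  flat <- matrix(S, ncol = dIn)        # rows: (site, T) entries
  z1 <- tanh(sweep(flat %*% mlp$W1, 2, mlp$b1, `+`))
  y <- drop(z1 %*% mlp$w2) + mlp$b2
  if (length(d) == 2) y else matrix(y, d[1], d[2])
}

# fast path used in training: a is a vector of raw site inputs for N =
# (site, anchor) entries, siteIdx maps each entry to its site row in E.
# Returns intermediates needed by the backward pass.
.siteLayerForward <- function(a, siteIdx, E, mlp, mode = "embedding") {
  if (mode == "identity") return(list(y = a, mode = mode))
  if (mode == "scalar") {
    # per-site trainable scale+offset stored in E[,1] and E[,2]
    return(list(y = E[siteIdx, 1] * a + E[siteIdx, 2], mode = mode))
  }
  Sv <- E[siteIdx, , drop = FALSE] * a            # N x d
  z1 <- sweep(Sv %*% mlp$W1, 2, mlp$b1, `+`)      # N x H
  u1 <- tanh(z1)
  y <- drop(u1 %*% mlp$w2) + mlp$b2
  list(y = y, Sv = Sv, u1 = u1, mode = mode)
}

# backward: dy is dL/dy (length N). Returns gradient contributions for E and
# the MLP plus dL/da (to be scattered back onto node states).
.siteLayerBackward <- function(dy, a, siteIdx, E, mlp, fw) {
  if (fw$mode == "identity")
    return(list(da = dy, dE = 0 * E, dW1 = NULL, db1 = NULL,
                dw2 = NULL, db2 = NULL))
  if (fw$mode == "scalar") {
    dE <- 0 * E
    dE[, 1] <- .rowsumAt(dy * a, siteIdx, nrow(E))
    dE[, 2] <- .rowsumAt(dy, siteIdx, nrow(E))
    return(list(da = dy * E[siteIdx, 1], dE = dE, dW1 = NULL, db1 = NULL,
                dw2 = NULL, db2 = NULL))
  }
  du1 <- tcrossprod(dy, mlp$w2)          # N x H
  dz1 <- du1 * (1 - fw$u1^2)
  dW1 <- crossprod(fw$Sv, dz1)           # d x H
  db1 <- colSums(dz1)
  dw2 <- drop(crossprod(fw$u1, dy))
  db2 <- sum(dy)
  dSv <- dz1 %*% t(mlp$W1)               # N x d
  da <- rowSums(dSv * E[siteIdx, , drop = FALSE])
  dEflat <- dSv * a
  dE <- .rowsumsAt(dEflat, siteIdx, nrow(E))
  list(da = da, dE = dE, dW1 = dW1, db1 = db1, dw2 = dw2, db2 = db2)
}

.rowsumAt <- function(v, idx, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

.rowsumsAt <- function(M, idx, n) {
  out <- matrix(0, n, ncol(M))
  agg <- rowsum(M, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Fit the phosphosite mapping layer in isolation
#'
#' Trains embeddings plus the shared MLP alone on given (node activity,
#' site intensity) pairs with Adam. This is the unit-level check that the
#' masked embedding layer can represent diverse node-to-site relations
#' (cosine, polynomial, sigmoid, square root) and recover the identity map.
#'
#' @param h numeric vector of raw site inputs (node activities), one per
#'   observation.
#' @param y numeric vector of target site intensities.
#' @param siteIdx integer site index per observation (default all site 1).
#' @param nSites number of sites (default `max(siteIdx)`).
#' @param d,hidden embedding dimension and MLP width.
#' @param epochs,lr Adam iterations over the full data and learning rate.
#' @param seed RNG seed.
#' @return list with trained `E`, `mlp`, a `predict(h, siteIdx)` function and
#'   the final mean squared error `mse`.
#' @export
trainSiteLayer <- function(h, y, siteIdx = rep(1L, length(h)),
                           nSites = max(siteIdx), d = 5, hidden = 16,
                           epochs = 2000, lr = 0.01, seed = 1) {
  op <- .withSeed(seed)
  on.exit(op())
  E <- matrix(stats::rnorm(nSites * d, sd = 0.3), nSites, d)
  mlp <- makeSiteMLP(d, hidden, seed = seed + 1)
  theta <- list(E = E, W1 = mlp$W1, b1 = mlp$b1, w2 = mlp$w2, b2 = mlp$b2)
  adam <- .adamInit(theta)
  N <- length(h)
  for (ep in seq_len(epochs)) {
    mlpCur <- list(W1 = theta$W1, b1 = theta$b1, w2 = theta$w2, b2 = theta$b2)
    fw <- .siteLayerForward(h, siteIdx, theta$E, mlpCur)
    res <- fw$y - y
    dy <- 2 * res / N
    bw <- .siteLayerBackward(dy, h, siteIdx, theta$E, mlpCur, fw)
    grads <- list(E = bw$dE, W1 = bw$dW1, b1 = bw$db1, w2 = bw$dw2,
                  b2 = bw$db2)
    st <- .adamStep(theta, grads, adam, lr)
    theta <- st$theta
    adam <- st$state
  }
  mlpFinal <- list(W1 = theta$W1, b1 = theta$b1, w2 = theta$w2, b2 = theta$b2)
  fw <- .siteLayerForward(h, siteIdx, theta$E, mlpFinal)
  Efinal <- theta$E
  list(E = Efinal, mlp = mlpFinal,
       predict = function(h, siteIdx = rep(1L, length(h)))
         .siteLayerForward(h, siteIdx, Efinal, mlpFinal)$y,
       mse = mean((fw$y - y)^2))
}
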