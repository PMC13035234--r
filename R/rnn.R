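#' @useDynLib phosphoRNN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Recurrent activation function
#'
#' The bounded, leaky activation of the signaling core: `leak * z` for
#' `z < 0` (so a strong negative drug input decays the node smoothly rather
#' than clipping), the identity on `[0, 0.5]`, and the saturating branch
#' `1 - 0.25/z` above 0.5, which is continuous, monotone non-decreasing and
#' bounded by 1. `f(0) = 0`.
#'
#' @param z numeric vector/matrix of pre-activations.
#' @param leak slope for negative inputs (default 0.01).
#' @return transformed values, same shape as `z`.
#' @export
rnnActivation <- function(z, leak = 0.01) {
  out <- z
  neg <- z < 0
  out[neg] <- leak * z[neg]
  hi <- z > 0.5
  out[hi] <- 1 - 0.25 / z[hi]
  out
}

# derivative from the activity value (see src/rnn_core.cpp)
.rnnActivationDeriv <- function(h, leak = 0.01) {
  d <- rep(1, length(h))
  d[h < 0] <- leak
  hi <- h > 0.5
  d[hi] <- 4 * (1 - h[hi])^2
  dim(d) <- dim(h)
  d
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.softplusInv <- function(y) ifelse(y > 30, y, log(expm1(y)))

#' Build per-sample node input vectors from a perturbation design
#'
#' Sustained-stimulation inputs, constant across recurrent steps: each
#' applied ligand contributes `+1 * ligand_weight` to its receptor nodes and
#' each applied drug a large negative `-5 * drug_weight` to its target nodes;
#' all other nodes receive 0. Weights are nonnegative by a softplus
#' reparameterization of the raw parameters, so the inhibitory sign is
#' carried by the fixed -5 constant, never by the trained weight. Unknown
#' drugs (absent from `drugRaw`) fall back to the initialization weight 1,
#' which is what zero-shot prediction of an untrained drug uses.
#'
#' @param design a [PerturbationDesign-class].
#' @param network a [SignedNetwork-class] giving the node order.
#' @param ligandRaw,drugRaw named numeric vectors of raw (pre-softplus)
#'   weights with names `"perturbation|node"`; missing entries default to
#'   `softplusInv(1)`.
#' @return nodes x samples numeric matrix of constant inputs.
#' @export
buildInputs <- function(design, network, ligandRaw = NULL, drugRaw = NULL) {
  nodes <- network@nodes
  B <- length(design@sampleIds)
  X <- matrix(0, length(nodes), B, dimnames = list(nodes, design@sampleIds))
  getw <- function(raw, key) {
    if (!is.null(raw) && key %in% names(raw)) .softplus(raw[[key]])
    else 1
  }
  for (lig in colnames(design@ligandMatrix)) {
    rec <- intersect(design@ligandReceptors[[lig]], nodes)
    if (length(rec) == 0)
      stop("ligand ", lig, " has no receptor node in the network")
    on <- design@ligandMatrix[, lig] != 0
    for (nd in rec)
      X[nd, on] <- X[nd, on] + 1 * getw(ligandRaw, paste0(lig, "|", nd))
  }
  for (dr in colnames(design@drugMatrix)) {
    if (!any(design@drugMatrix[, dr] != 0)) next
    tgt <- intersect(design@drugTargets[[dr]], nodes)
    if (length(tgt) == 0)
      stop("drug ", dr, " has no surviving target node in the network")
    on <- design@drugMatrix[, dr] != 0
    for (nd in tgt)
      X[nd, on] <- X[nd, on] - 5 * getw(drugRaw, paste0(dr, "|", nd))
  }
  X
}

#' Simulate the recurrent signaling trajectory
#'
#' Iterates `h_{t+1} = f(W h_t + b + x)` for `L` steps with
#' `h_0 = f(b + x)`, where `f` is [rnnActivation()] and `x` the constant
#' per-sample input. Steps are 0-based: slice `t+1` of the result holds
#' `h_t`.
#'
#' @param W nodes x nodes weight matrix (target x source).
#' @param b per-node bias vector.
#' @param inputs nodes x samples input matrix (see [buildInputs()]); a
#'   vector is treated as a single sample.
#' @param L number of recurrent steps (>= 1).
#' @param leak negative-branch slope of the activation.
#' @return numeric array nodes x samples x L of states.
#' @export
simulateTrajectory <- function(W, b, inputs, L = 150, leak = 0.01) {
  if (is.vector(inputs)) inputs <- matrix(inputs, ncol = 1)
  stopifnot(L >= 1, nrow(W) == ncol(W), nrow(inputs) == nrow(W),
            length(b) == nrow(W))
  if (!all(is.finite(W)) || !all(is.finite(b)) || !all(is.finite(inputs)))
    stop("non-finite parameters or inputs")
  H <- .rnnForwardCpp(W, as.numeric(b), inputs, as.integer(L), leak)
  dimnames(H) <- list(rownames(W), colnames(inputs), NULL)
  H
}
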