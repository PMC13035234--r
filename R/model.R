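#' Initialize a composed signaling model
#'
#' Builds a [PhosphoModel-class]: recurrent weights on the prior-knowledge
#' support (small magnitudes with the curated signs, rescaled so the
#' magnitude matrix starts with a contractive spectral radius), per-node
#' biases, softplus-parameterized ligand/drug input weights initialized to
#' an effective weight of 1, small random site embeddings, a shared MLP and
#' time-map parameters giving initially uniform anchors.
#'
#' Sites whose assigned protein has no node in the (pruned) network are
#' dropped with a message rather than an error.
#'
#' @param network a [SignedNetwork-class].
#' @param assignment a [SiteAssignment-class].
#' @param design a [PerturbationDesign-class] naming the ligands/drugs the
#'   model will train input weights for.
#' @param times experimental sampling times (minutes) the time map anchors.
#' @param L total recurrent steps (default 150).
#' @param embedDim site-embedding dimension (default 5).
#' @param hiddenWidth MLP hidden width (default 16).
#' @param seed RNG seed for initialization.
#' @param siteMapMode `"embedding"` (full layer), `"scalar"` (per-site scale
#'   and offset) or `"identity"` (site output = node activity); the reduced
#'   modes realize the ablation ladder.
#' @param timeMapVariant `"exp"` or `"literal"`, see [computeAnchors()].
#' @param leak activation leak slope.
#' @param initSpectral spectral radius of `|W|` after init rescaling.
#' @return a [PhosphoModel-class].
#' @export
phosphoModel <- function(network, assignment, design, times, L = 150,
                         embedDim = 5, hiddenWidth = 16, seed = 1,
                         siteMapMode = c("embedding", "scalar", "identity"),
                         timeMapVariant = "exp", leak = 0.01,
                         initSpectral = 0.8) {
  siteMapMode <- match.arg(siteMapMode)
  op <- .withSeed(seed)
  on.exit(op())
  keep <- assignment@siteNodes %in% network@nodes
  if (!all(keep)) {
    message(sum(!keep), " site(s) dropped: protein not in the network")
    assignment <- methods::new("SiteAssignment",
                               siteIds = assignment@siteIds[keep],
                               siteNodes = assignment@siteNodes[keep])
  }
  n <- length(network@nodes)
  S <- length(assignment@siteIds)
  A <- network@adjacency
  mag <- matrix(stats::runif(n * n, 0.5, 1.5), n, n) * A
  # inhibitory edges start small so every node's initial net input under
  # stimulation is positive: node states then launch on the positive
  # activation branch (negative states are only reachable transiently
  # through the leaky branch), which anchors the site maps to positive
  # slopes instead of locking random nodes into a sign-inverted
  # state/slope solution the data cannot distinguish
  mag[network@signs < 0] <- 0.25 * mag[network@signs < 0]
  # balance incoming magnitudes per node so the initial network already
  # propagates ligand input through deep cascades; rescaled to a
  # contractive spectral radius of the magnitude matrix
  inSum <- rowSums(mag)
  mag <- mag * ifelse(inSum > 0, 1 / inSum, 0)
  W <- network@signs * mag
  if (any(A == 1)) {
    rho <- max(Mod(eigen(abs(W), only.values = TRUE)$values))
    if (rho > 0) W <- W * (initSpectral / rho)
  }
  b <- stats::rnorm(n, sd = 0.01)
  raw0 <- .softplusInv(1)
  pairNames <- function(perts, targets) {
    unlist(lapply(perts, function(p)
      paste0(p, "|", intersect(targets[[p]], network@nodes))))
  }
  ligs <- colnames(design@ligandMatrix)
  drugs <- colnames(design@drugMatrix)
  ligandRaw <- stats::setNames(rep(raw0, length(pairNames(ligs, design@ligandReceptors))),
                               pairNames(ligs, design@ligandReceptors))
  drugRaw <- stats::setNames(rep(raw0, length(pairNames(drugs, design@drugTargets))),
                             pairNames(drugs, design@drugTargets))
  dE <- if (siteMapMode == "scalar") 2 else embedDim
  # embeddings start near a shared direction so every site map opens with a
  # consistently oriented slope: early training then fits rising
  # trajectories by activating nodes instead of flipping individual site
  # maps into sign-inverted solutions that break extrapolation
  E <- matrix(0.5 + stats::rnorm(S * dE, sd = 0.1), S, dE)
  if (siteMapMode == "scalar") { E[, 1] <- 1; E[, 2] <- 0 }
  mlp <- makeSiteMLP(embedDim, hiddenWidth, seed = seed + 1)
  K <- length(times)
  params <- list(W = W, b = b, ligandRaw = ligandRaw, drugRaw = drugRaw,
                 E = E, W1 = mlp$W1, b1 = mlp$b1, w2 = mlp$w2, b2 = mlp$b2,
                 deltaRaw = rep(0, K), uRaw = 0, alpha = 0)
  methods::new("PhosphoModel", network = network, assignment = assignment,
               ligands = as.character(ligs), drugs = as.character(drugs),
               times = as.numeric(times), nSteps = L, params = params,
               settings = list(leak = leak, embedDim = embedDim,
                               hiddenWidth = hiddenWidth,
                               timeMapVariant = timeMapVariant,
                               maskActive = TRUE, siteMapMode = siteMapMode,
                               fixedAnchors = NULL, seed = seed))
}

# effective recurrent weight matrix: masked by the prior unless the
# fully connected variant is active
.effectiveW <- function(model) {
  if (isTRUE(model@settings$maskActive))
    model@params$W * model@network@adjacency
  else model@params$W
}

.modelAnchors <- function(model) {
  fx <- model@settings$fixedAnchors
  if (!is.null(fx)) return(fx)
  p <- model@params
  u <- computeUpperBound(p$uRaw, model@nSteps)
  m <- computeAnchors(p$deltaRaw, p$alpha, u,
                      variant = model@settings$timeMapVariant)
  pmin(m, model@nSteps - 1)
}

#' Current time-map anchors of a model
#'
#' @param model a [PhosphoModel-class].
#' @return numeric vector of fractional-step anchors, one per model time.
#' @export
modelAnchors <- function(model) .modelAnchors(model)

#' Fix the time-map anchors of a model
#'
#' Freezes the time map at the given fractional steps (e.g. a one-to-one map
#' or externally estimated anchors); the time-map parameters stop training.
#' Pass `NULL` to unfreeze.
#'
#' @param model a [PhosphoModel-class].
#' @param anchors numeric vector, one fractional step per model time, or
#'   `NULL`.
#' @return the updated model.
#' @export
fixAnchors <- function(model, anchors) {
  if (!is.null(anchors)) {
    stopifnot(length(anchors) == length(model@times),
              all(anchors >= 0), all(anchors <= model@nSteps - 1))
  }
  model@settings$fixedAnchors <- anchors
  model
}

#' Switch a model to the fully connected (no prior network) variant
#'
#' Replaces the prior-knowledge adjacency mask with an all-ones mask: every
#' node may influence every node and all n^2 signaling weights train freely.
#' The sign-consistency penalty is disabled (there are no curated modes of
#' action for the added connections). The masked family is nested in this
#' one: zeroing all weights outside the prior support recovers the prior
#' model's trajectories exactly.
#'
#' @param model a [PhosphoModel-class].
#' @return the fully connected model; its parameter count is reported.
#' @export
makeNoPknVariant <- function(model) {
  model@settings$maskActive <- FALSE
  n <- length(model@network@nodes)
  message("fully connected variant: ", n * n, " trainable signaling weights")
  model
}

# forward pass for a set of samples. X: nodes x B inputs. Returns all
# intermediates needed for the backward pass.
.modelForward <- function(model, X, anchors = NULL) {
  W <- .effectiveW(model)
  p <- model@params
  L <- model@nSteps
  H <- .rnnForwardCpp(W, p$b, X, as.integer(L), model@settings$leak)
  if (is.null(anchors)) anchors <- .modelAnchors(model)
  n <- dim(H)[1]; B <- dim(H)[2]; K <- length(anchors)
  f <- floor(anchors); dm <- anchors - f
  lo <- f + 1L; hi <- pmin(f + 2L, L)
  hA <- array(0, c(n, B, K))
  for (k in seq_len(K))
    hA[, , k] <- (1 - dm[k]) * H[, , lo[k]] + dm[k] * H[, , hi[k]]
  nodeIdx <- match(model@assignment@siteNodes, model@network@nodes)
  Ssites <- length(nodeIdx)
  # a[(site, sample, anchor)] flattened with site fastest
  a <- array(hA[nodeIdx, , , drop = FALSE], c(Ssites, B, K))
  mlp <- list(W1 = p$W1, b1 = p$b1, w2 = p$w2, b2 = p$b2)
  siteIdx <- rep(seq_len(Ssites), B * K)
  fw <- .siteLayerForward(as.numeric(a), siteIdx, p$E, mlp,
                          mode = model@settings$siteMapMode)
  Y <- array(fw$y, c(Ssites, B, K))
  list(H = H, anchors = anchors, f = f, dm = dm, lo = lo, hi = hi, hA = hA,
       a = a, fw = fw, Y = Y, nodeIdx = nodeIdx, siteIdx = siteIdx,
       W = W, X = X, mlp = mlp)
}

#' Predict phosphosite intensities for a perturbation design
#'
#' Runs the trained model forward: builds inputs from the design (drugs the
#' model was not trained on use the default input weight of 1, which is the
#' zero-shot mechanism), simulates the recurrent trajectory, reads it at the
#' time-map anchors and applies the phosphosite mapping layer.
#'
#' @param model a [PhosphoModel-class].
#' @param design a [PerturbationDesign-class].
#' @param anchors optional override of the fractional-step anchors.
#' @return a [PhosphoTimeCourse-class] of predictions (all entries observed).
#' @export
predictModel <- function(model, design, anchors = NULL) {
  X <- buildInputs(design, model@network, model@params$ligandRaw,
                   model@params$drugRaw)
  fwd <- .modelForward(model, X, anchors = anchors)
  K <- length(fwd$anchors)
  vals <- aperm(fwd$Y, c(1, 3, 2))      # sites x K x samples
  methods::new("PhosphoTimeCourse", values = vals,
               mask = array(TRUE, dim(vals)),
               siteIds = model@assignment@siteIds,
               times = if (length(model@times) == K) model@times
                       else as.numeric(seq_len(K) - 1),
               sampleIds = design@sampleIds)
}

#' Serialize a model to a JSON checkpoint
#'
#' Portable JSON container with an explicit `schema_version` field; numeric
#' arrays are stored with full precision and restored bit-compatibly on read.
#'
#' @param model a [PhosphoModel-class].
#' @param path output file.
#' @export
saveModel <- function(model, path) {
  params <- model@params
  # named vectors go out as JSON objects so auto_unbox cannot strip the
  # perturbation|node keys off length-one weight vectors
  params$ligandRaw <- as.list(params$ligandRaw)
  params$drugRaw <- as.list(params$drugRaw)
  payload <- list(
    schema_version = 1L,
    nodes = model@network@nodes,
    edges = model@network@edges,
    siteIds = model@assignment@siteIds,
    siteNodes = model@assignment@siteNodes,
    ligands = model@ligands, drugs = model@drugs,
    times = model@times, nSteps = model@nSteps,
    params = params, settings = model@settings)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Restore a model from a JSON checkpoint
#'
#' @param path checkpoint written by [saveModel()].
#' @return a [PhosphoModel-class].
#' @export
loadModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) || x$schema_version != 1)
    stop("unsupported checkpoint schema version")
  net <- signedNetwork(as.data.frame(x$edges), nodes = x$nodes)
  p <- x$params
  n <- length(x$nodes)
  asMat <- function(m, nr, nc)
    if (is.matrix(m)) m else matrix(unlist(m), nr, nc, byrow = TRUE)
  p$W <- asMat(p$W, n, n)
  dimnames(p$W) <- list(x$nodes, x$nodes)
  S <- length(x$siteIds)
  p$E <- asMat(p$E, S, length(unlist(p$E)) / S)
  H <- length(p$b1)
  p$W1 <- asMat(p$W1, length(unlist(p$W1)) / H, H)
  emptyRaw <- stats::setNames(numeric(0), character(0))
  p$ligandRaw <- if (length(p$ligandRaw)) unlist(p$ligandRaw) else emptyRaw
  p$drugRaw <- if (length(p$drugRaw)) unlist(p$drugRaw) else emptyRaw
  st <- x$settings
  if (!is.null(st$fixedAnchors) && length(st$fixedAnchors) == 0)
    st$fixedAnchors <- NULL
  methods::new("PhosphoModel", network = net,
               assignment = methods::new("SiteAssignment",
                                         siteIds = x$siteIds,
                                         siteNodes = x$siteNodes),
               ligands = as.character(x$ligands),
               drugs = as.character(x$drugs),
               times = x$times, nSteps = x$nSteps, params = p,
               settings = st)
}
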