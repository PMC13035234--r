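#' Training configuration
#'
#' Defaults follow the settings used throughout: learning rate 2e-3, 5000
#' epochs, L2 weight 1e-5, five power iterations for the spectral-radius
#' estimate, Adam with warm restarts and cosine annealing (restart period
#' epochs/5), smooth gradient clipping and additive Gaussian gradient noise
#' whose standard deviation is `noiseCoef` times the current learning rate
#' (so it decays with the schedule by construction). Mini-batches contain
#' all timepoints of a single sample to preserve temporal coherence.
#'
#' @param learningRate base Adam learning rate.
#' @param epochs training epochs (>= 1).
#' @param l2 L2 regularization weight on parameters.
#' @param powerIterations power iterations per spectral-radius estimate.
#' @param spectralTarget target spectral radius rho* (penalty-free below).
#' @param spectralWeight weight of the spectral penalty.
#' @param signWeight weight of the mode-of-action sign penalty.
#' @param clipMax smooth gradient-clipping scale g_max.
#' @param noiseCoef gradient-noise coefficient (sd = noiseCoef * lr).
#' @param restartPeriod warm-restart period in epochs (default epochs/5).
#' @param lrMin floor of the cosine schedule.
#' @param seed run seed (controls batch shuffling and gradient noise).
#' @return a list of class `trainingConfig`.
#' @export
trainingConfig <- function(learningRate = 2e-3, epochs = 5000, l2 = 1e-5,
                           powerIterations = 5, spectralTarget = 0.95,
                           spectralWeight = 10, signWeight = 1,
                           clipMax = 5, noiseCoef = 1,
                           restartPeriod = NULL, lrMin = 0, seed = 1) {
  stopifnot(epochs >= 1, learningRate >= 0, l2 >= 0, powerIterations >= 1,
            spectralWeight >= 0, signWeight >= 0, clipMax > 0,
            noiseCoef >= 0)
  if (is.null(restartPeriod)) restartPeriod <- max(1, ceiling(epochs / 5))
  structure(list(learningRate = learningRate, epochs = epochs, l2 = l2,
                 powerIterations = powerIterations,
                 spectralTarget = spectralTarget,
                 spectralWeight = spectralWeight, signWeight = signWeight,
                 clipMax = clipMax, noiseCoef = noiseCoef,
                 restartPeriod = restartPeriod, lrMin = lrMin, seed = seed),
            class = "trainingConfig")
}

#' Masked mean squared error
#'
#' Mean of squared prediction errors over observed entries only; missing
#' measurements and invalid site-node pairs are excluded through the mask.
#'
#' @param pred,obs numeric arrays of equal shape.
#' @param mask logical array of the same shape; TRUE where observed.
#' @return scalar mean squared error.
#' @export
maskedMSE <- function(pred, obs, mask) {
  stopifnot(identical(dim(pred), dim(obs)) ||
              length(pred) == length(obs))
  if (!any(mask)) stop("no observed entries")
  mean((pred[mask] - obs[mask])^2)
}

#' Mode-of-action sign violation penalty
#'
#' `sum over edges of relu(-sign * W)^2`: zero iff every trained weight
#' agrees in sign with the curated mode of action (or is zero); its gradient
#' pushes violating weights back toward zero.
#'
#' @param W weight matrix.
#' @param signs mode-of-action matrix in \{-1, 0, +1\} (zero off-support).
#' @return scalar penalty.
#' @export
signViolationPenalty <- function(W, signs) {
  stopifnot(identical(dim(W), dim(signs)))
  sum(pmax(-signs * W, 0)[signs != 0]^2)
}

.signPenaltyGrad <- function(W, signs) {
  v <- pmax(-signs * W, 0)
  v[signs == 0] <- 0
  -2 * signs * v
}

#' Spectral-radius penalty
#'
#' `relu(rho_hat(W) - rho*)^2` with the power-iteration estimate of
#' [spectralRadius()]; zero while the estimated radius stays below the
#' target, so it only activates to pull non-contractive dynamics back.
#'
#' @param W square weight matrix.
#' @param target target spectral radius rho*.
#' @param nIter power iterations for the estimate.
#' @return scalar penalty.
#' @export
spectralPenalty <- function(W, target = 0.95, nIter = 5) {
  max(spectralRadius(W, nIter) - target, 0)^2
}

# parameters that receive L2 regularization (time-map parameters excluded so
# anchors can move freely along the step axis)
.L2_PARAMS <- c("W", "b", "ligandRaw", "drugRaw", "E", "W1", "b1", "w2", "b2")

# masked-MSE loss and its gradient w.r.t. every trainable parameter for one
# sample (mini-batch): forward through RNN, soft indexing at the anchors,
# site layer; backward through the site layer, scatter onto the bracketing
# integer steps, BPTT, then chain rules for input weights and the time map.
# obs/mk: sites x anchors matrices. appliedLig/appliedDrug: character
# vectors of perturbations active in this sample. Penalties are not
# included. Returns list(mse, grads).
.sampleLossGrad <- function(model, X, obs, mk, appliedLig, appliedDrug,
                            support = NULL) {
  theta <- model@params
  net <- model@network
  n <- length(net@nodes)
  L <- model@nSteps
  nodeIdx <- match(model@assignment@siteNodes, net@nodes)
  Ssites <- length(nodeIdx)
  K <- length(obs) / Ssites
  obs <- matrix(obs, Ssites, K)
  mk <- matrix(mk, Ssites, K)
  siteIdx <- rep(seq_len(Ssites), K)
  maskActive <- isTRUE(model@settings$maskActive)
  fwd <- .modelForward(model, X)
  nObs <- sum(mk)
  if (nObs == 0) stop("no observed entries")
  pred <- matrix(fwd$Y, Ssites, K)
  res <- (pred - obs) * mk
  mse <- sum(res^2) / nObs
  dy <- as.numeric(2 * res / nObs)

  bw <- .siteLayerBackward(dy, as.numeric(fwd$a), siteIdx, theta$E,
                           fwd$mlp, fwd$fw)
  dhA <- .rowsumsAt(matrix(bw$da, Ssites, K), nodeIdx, n)
  G <- array(0, c(n, 1, L))
  dmVec <- numeric(K)
  Hm <- matrix(fwd$H, n, L)
  for (k in seq_len(K)) {
    G[, 1, fwd$lo[k]] <- G[, 1, fwd$lo[k]] + (1 - fwd$dm[k]) * dhA[, k]
    G[, 1, fwd$hi[k]] <- G[, 1, fwd$hi[k]] + fwd$dm[k] * dhA[, k]
    dmVec[k] <- sum(dhA[, k] * (Hm[, fwd$hi[k]] - Hm[, fwd$lo[k]]))
  }
  rb <- .rnnBackwardCpp(fwd$W, fwd$H, G, model@settings$leak, support)
  dW <- rb$dW
  if (maskActive && is.null(support)) dW <- dW * net@adjacency

  grads <- list(W = dW, b = drop(rb$db),
                ligandRaw = 0 * theta$ligandRaw,
                drugRaw = 0 * theta$drugRaw,
                E = bw$dE,
                W1 = bw$dW1, b1 = bw$db1, w2 = bw$dw2, b2 = bw$db2,
                deltaRaw = NULL, uRaw = NULL, alpha = NULL)
  dX <- stats::setNames(rb$dX[, 1], net@nodes)
  pairSplit <- function(nm) do.call(rbind, strsplit(nm, "|", fixed = TRUE))
  if (length(theta$ligandRaw) && length(appliedLig)) {
    ps <- pairSplit(names(theta$ligandRaw))
    on <- ps[, 1] %in% appliedLig
    grads$ligandRaw[on] <- dX[ps[on, 2]] * 1 * stats::plogis(theta$ligandRaw[on])
  }
  if (length(theta$drugRaw) && length(appliedDrug)) {
    ps <- pairSplit(names(theta$drugRaw))
    on <- ps[, 1] %in% appliedDrug
    grads$drugRaw[on] <- dX[ps[on, 2]] * (-5) * stats::plogis(theta$drugRaw[on])
  }
  if (is.null(model@settings$fixedAnchors)) {
    ag <- .anchorsWithGrad(theta$deltaRaw, theta$alpha, theta$uRaw, L,
                           model@settings$timeMapVariant)
    dmVec[ag$anchors > L - 1] <- 0
    grads$deltaRaw <- drop(dmVec %*% ag$dDelta)
    grads$alpha <- sum(dmVec * ag$dAlpha)
    grads$uRaw <- sum(dmVec * ag$dURaw)
  }
  list(mse = mse, grads = grads, Weff = fwd$W)
}

#' Train the composed model
#'
#' End-to-end training of recurrent core, phosphosite mapping and time
#' mapping with hand-derived backpropagation (BPTT through the recurrent
#' steps). The objective is the masked MSE plus L2, sign-consistency and
#' spectral-radius penalties; optimization is Adam under a warm-restart
#' cosine schedule with smooth gradient clipping and decaying gradient
#' noise. Each mini-batch is one sample's full time series; sample order is
#' shuffled every epoch under the run seed. Reproducible: the same seed
#' yields an identical loss report and parameters.
#'
#' @param model a [PhosphoModel-class] (see [phosphoModel()]).
#' @param timecourse a [PhosphoTimeCourse-class] with the model's sites and
#'   times.
#' @param design a [PerturbationDesign-class] aligned with the time course's
#'   samples.
#' @param config a [trainingConfig()].
#' @param verbose print progress every 100 epochs.
#' @return list with `model` (trained) and `loss`, a per-epoch data.frame of
#'   loss components (`mse`, `l2`, `sign`, `spectral`, `total`).
#' @export
trainModel <- function(model, timecourse, design, config = trainingConfig(),
                       verbose = FALSE) {
  op <- .withSeed(config$seed)
  on.exit(op())
  sIdxData <- match(model@assignment@siteIds, timecourse@siteIds)
  if (anyNA(sIdxData)) stop("time course is missing model sites")
  if (length(timecourse@times) != length(model@times) ||
      any(timecourse@times != model@times))
    stop("time course times do not match the model's times")
  B <- length(design@sampleIds)
  stopifnot(identical(design@sampleIds, timecourse@sampleIds))
  obsAll <- timecourse@values[sIdxData, , , drop = FALSE]
  maskAll <- timecourse@mask[sIdxData, , , drop = FALSE]
  if (!any(maskAll)) stop("no observed entries")

  net <- model@network
  A <- net@adjacency
  Smat <- net@signs
  maskActive <- isTRUE(model@settings$maskActive)
  # support indices of W: penalties, L2 and gradient noise for W act there
  # only (off-support entries are identically zero under the prior mask)
  supIdx <- if (maskActive) which(A == 1) else seq_along(A)
  signSup <- Smat[supIdx]
  supMat <- if (maskActive)
    matrix(as.integer(which(A == 1, arr.ind = TRUE) - 1L), ncol = 2)
  else NULL
  theta <- model@params
  # the optimizer sees W as its support vector; the full matrix is kept in
  # sync for the forward/backward passes
  thetaOpt <- theta
  thetaOpt$W <- theta$W[supIdx]
  adam <- .adamInit(thetaOpt)

  # per-sample applied perturbations for input-weight gradients
  appliedLig <- lapply(seq_len(B), function(s)
    colnames(design@ligandMatrix)[design@ligandMatrix[s, ] != 0])
  appliedDrug <- lapply(seq_len(B), function(s)
    colnames(design@drugMatrix)[design@drugMatrix[s, ] != 0])

  report <- data.frame(epoch = seq_len(config$epochs), mse = NA_real_,
                       l2 = NA_real_, sign = NA_real_, spectral = NA_real_,
                       total = NA_real_)
  for (epoch in seq_len(config$epochs)) {
    lr <- .cosineRestartLR(epoch, config$learningRate, config$restartPeriod,
                           config$lrMin)
    ord <- sample.int(B)
    comp <- c(mse = 0, l2 = 0, sign = 0, spectral = 0)
    for (s in ord) {
      curModel <- model
      curModel@params <- theta
      X <- buildInputs(design[s], net, theta$ligandRaw, theta$drugRaw)
      sg <- .sampleLossGrad(curModel, X, obsAll[, , s], maskAll[, , s],
                            appliedLig[[s]], appliedDrug[[s]], supMat)
      mse <- sg$mse
      grads <- sg$grads
      Weff <- sg$Weff

      # penalties (evaluated on the current effective weights)
      wSup <- Weff[supIdx]
      l2val <- config$l2 *
        (sum(wSup^2) + sum(vapply(setdiff(.L2_PARAMS, "W"), function(nm)
          sum(theta[[nm]]^2), numeric(1))))
      signViol <- if (maskActive && config$signWeight > 0)
        pmax(-signSup * wSup, 0) else 0
      signval <- config$signWeight * sum(signViol^2)
      sp <- .spectralRadiusGrad(Weff, config$powerIterations)
      over <- max(sp$value - config$spectralTarget, 0)
      spectralval <- config$spectralWeight * over^2

      # regularizer gradients
      for (nm in setdiff(.L2_PARAMS, "W"))
        if (!is.null(grads[[nm]]))
          grads[[nm]] <- grads[[nm]] + 2 * config$l2 * theta[[nm]]
      gW <- grads$W[supIdx] + 2 * config$l2 * wSup
      if (maskActive && config$signWeight > 0)
        gW <- gW - config$signWeight * 2 * signSup * signViol
      if (over > 0)
        gW <- gW + config$spectralWeight * 2 * over * sp$grad[supIdx]
      grads$W <- gW

      comps <- c(mse = mse, l2 = l2val, sign = signval,
                 spectral = spectralval)
      if (any(!is.finite(comps))) {
        bad <- names(comps)[!is.finite(comps)][1]
        stop("non-finite loss component at epoch ", epoch, ": ", bad)
      }
      comp <- comp + comps

      # smooth clipping + decaying gradient noise, then Adam; noise for W
      # is drawn on the support only (off-support entries stay zero)
      flat <- .flattenGrads(grads[!vapply(grads, is.null, logical(1))])
      scale <- .smoothClipScale(sqrt(sum(flat^2)), config$clipMax)
      sdNoise <- config$noiseCoef * lr
      for (nm in names(grads)) {
        if (is.null(grads[[nm]])) next
        g <- grads[[nm]] * scale
        if (sdNoise > 0)
          g <- g + stats::rnorm(length(g), sd = sdNoise)
        grads[[nm]] <- g
      }
      st <- .adamStep(thetaOpt, grads, adam, lr)
      thetaOpt <- st$theta
      adam <- st$state
      Wfull <- theta$W
      Wfull[supIdx] <- thetaOpt$W
      theta <- thetaOpt
      theta$W <- Wfull
    }
    comp <- comp / B
    report[epoch, 2:6] <- c(comp, sum(comp))
    if (verbose && epoch %% 100 == 0)
      message(sprintf("epoch %d  mse %.5f  total %.5f", epoch, comp["mse"],
                      sum(comp)))
  }
  model@params <- theta
  list(model = model, loss = report)
}

#' Write a loss report as CSV
#'
#' @param loss the per-epoch loss data.frame from [trainModel()].
#' @param path output CSV file.
#' @export
writeLossCurve <- function(loss, path) {
  utils::write.csv(loss, path, row.names = FALSE)
  invisible(path)
}
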