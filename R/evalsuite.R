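#' Baseline-normalize trajectories by their time-zero value
#'
#' Subtracts each (site, sample) trajectory's timepoint-zero value so every
#' trajectory starts at zero; removes baseline offsets before correlating
#' dynamics. Idempotent.
#'
#' @param tc a [PhosphoTimeCourse-class] whose first time is 0.
#' @return the baseline-subtracted time course.
#' @export
baselineSubtractT0 <- function(tc) {
  t0 <- which(tc@times == 0)
  if (length(t0) != 1) stop("time course must contain a unique t = 0")
  base <- tc@values[, t0, , drop = FALSE]
  vals <- sweep(tc@values, c(1, 3), array(base, dim(base)[c(1, 3)]), `-`)
  phosphoTimeCourse(vals, tc@siteIds, tc@times, tc@sampleIds, tc@mask)
}

#' Pearson correlation of differential responses
#'
#' Correlates control-subtracted predictions against control-subtracted
#' observations: `cor(pred - predControl, obs - obsControl)`. Subtracting
#' the matched control focuses the score on perturbation-induced change
#' rather than shared stimulation signal. With zero controls this is the
#' plain Pearson correlation. Degenerate (zero-variance) difference vectors
#' are an error, never silently zero.
#'
#' @param pred,obs aligned numeric vectors (>= 3 values).
#' @param predControl,obsControl matched control vectors (default 0).
#' @return Pearson r.
#' @export
pearsonDifferential <- function(pred, obs, predControl = 0, obsControl = 0) {
  .pearson(pred - predControl, obs - obsControl)
}

#' Naive estimator for a held-out drug
#'
#' Predicts the held-out drug's differential response as the element-wise
#' mean of the remaining drugs' observed responses: the baseline any model
#' must beat in the zero-shot setting.
#'
#' @param heldOut drug identifier (a row of `responses`).
#' @param responses numeric matrix, drugs x features, of observed
#'   (control-subtracted) responses; rownames are drug ids.
#' @return numeric vector: the mean over remaining drugs.
#' @export
naiveDrugBaseline <- function(heldOut, responses) {
  stopifnot(is.matrix(responses), heldOut %in% rownames(responses))
  rest <- responses[setdiff(rownames(responses), heldOut), , drop = FALSE]
  if (nrow(rest) == 0) stop("no remaining drugs to average")
  colMeans(rest)
}

#' Bootstrap comparison of two predictors' correlations
#'
#' Resamples phosphosites with replacement and compares the Pearson
#' correlation with the observations achieved by predictor A (the model)
#' against predictor B (the baseline) in each resample:
#' `p = (1 + #\{r_B > r_A\} + 0.5 #\{r_B = r_A\}) / (nBoot + 1)` (add-one
#' smoothing keeps p > 0; exact ties split, so comparing a predictor with
#' itself gives p near 0.5). Sites are the replication unit. Inputs are
#' difference (control-subtracted) vectors.
#'
#' @param predA,predB,obs aligned numeric vectors (>= 3 sites).
#' @param nBoot bootstrap resamples (>= 1e5 to resolve p < 1e-5).
#' @param seed RNG seed.
#' @return the bootstrap p-value.
#' @export
bootstrapCompare <- function(predA, predB, obs, nBoot = 1e5, seed = 1) {
  nS <- length(obs)
  if (nS < 3) stop("need at least 3 sites")
  stopifnot(length(predA) == nS, length(predB) == nS)
  op <- .withSeed(seed)
  on.exit(op())
  wins <- 0
  for (i in seq_len(nBoot)) {
    idx <- sample.int(nS, nS, replace = TRUE)
    o <- obs[idx]
    if (stats::sd(o) == 0) { wins <- wins + 0.5; next }
    rA <- suppressWarnings(stats::cor(predA[idx], o))
    rB <- suppressWarnings(stats::cor(predB[idx], o))
    if (is.na(rA)) rA <- 0
    if (is.na(rB)) rB <- 0
    # exact ties count half, so identical predictors give p ~ 0.5
    wins <- wins + (rB > rA) + 0.5 * (rB == rA)
  }
  (1 + wins) / (nBoot + 1)
}

#' ROC/AUC for up- and down-regulated phosphosite calls
#'
#' Labels sites from the observed centered differences with a fold-change
#' threshold in both directions (clearly up: `obs >= fc`, clearly down:
#' `obs <= -fc`, on the log2-like centered scale used throughout) and treats
#' the predictions as continuous scores; reports one AUC per direction.
#' Inputs must already be centered (e.g. by subtracting each site's mean
#' across training samples). A direction lacking positives or negatives has
#' an undefined AUC, reported as `NA`.
#'
#' @param pred,obs aligned numeric vectors of centered differences.
#' @param fcThreshold fold-change threshold (default 1).
#' @return named numeric vector `c(up = ..., down = ...)`.
#' @export
updownROC <- function(pred, obs, fcThreshold = 1) {
  aucDir <- function(labels, scores) {
    if (sum(labels) == 0 || sum(!labels) == 0) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                   quiet = TRUE, direction = "<",
                                   levels = c(FALSE, TRUE))))
  }
  c(up = aucDir(obs >= fcThreshold, pred),
    down = aucDir(obs <= -fcThreshold, -pred))
}

# pooled control-subtracted correlation for one held-out sample:
# (pred_drug - pred_ctrl) vs (obs_drug - obs_ctrl) over sites x times > 0
.zeroShotR <- function(predTc, obsTc, heldSample, controlSample = "CTRL") {
  tsel <- which(predTc@times > 0)
  ph <- predTc@values[, tsel, match(heldSample, predTc@sampleIds)]
  pc <- predTc@values[, tsel, match(controlSample, predTc@sampleIds)]
  oh <- obsTc@values[, tsel, match(heldSample, obsTc@sampleIds)]
  oc <- obsTc@values[, tsel, match(controlSample, obsTc@sampleIds)]
  pearsonDifferential(as.numeric(ph), as.numeric(oh), as.numeric(pc),
                      as.numeric(oc))
}

#' Temporal down-sampling protocol on step-resolved synthetic data
#'
#' Generates a step-resolved synthetic dataset over the first `window`
#' recurrent steps (where the primary signaling dynamics occur), then for
#' each anchor fraction trains the model with that percentage of uniformly
#' spaced timepoint anchors (anchors fixed one-to-one to the provided
#' steps) and scores interpolation as the pooled Pearson correlation between
#' time-zero-subtracted predictions and observations on the withheld steps.
#'
#' @param gt a [SyntheticGroundTruth-class] with sites assigned.
#' @param fractions numeric fractions of the `window` timepoints provided
#'   during training; a fraction yielding fewer than 2 anchors is an error.
#' @param window number of leading recurrent steps modeled (default 30).
#' @param nDrugs number of synthetic drug samples alongside the control.
#' @param epochs training epochs.
#' @param seeds one run per seed (training init/shuffling and noise).
#' @param config base [trainingConfig()] overridden per run.
#' @return data.frame with columns `fraction`, `nAnchors`, `seed`, `r`.
#' @export
runDownsamplingProtocol <- function(gt, fractions = c(0.2, 0.4, 0.8),
                                    window = 30, nDrugs = 4, epochs = 400,
                                    seeds = 1:3,
                                    config = trainingConfig()) {
  nA <- vapply(fractions, function(f) round(f * window), numeric(1))
  if (any(nA < 2)) stop("fraction yields fewer than 2 anchors")
  drugs <- utils::head(names(gt@drugTargets), nDrugs)
  out <- list()
  for (seed in seeds) {
    ds <- generateTimecourse(gt, drugs, times = 0:(window - 1), L = window,
                             anchors = 0:(window - 1), seed = gt@seed + seed)
    obs0 <- baselineSubtractT0(ds@timecourse)
    for (i in seq_along(fractions)) {
      steps <- unique(round(seq(0, window - 1, length.out = nA[i])))
      tcTrain <- subsetTimes(ds@timecourse, steps)
      model <- phosphoModel(gt@network, ds@assignment, ds@design,
                            times = steps, L = window, seed = seed)
      model <- fixAnchors(model, steps)
      cfg <- config
      cfg$epochs <- epochs
      cfg$restartPeriod <- max(1, ceiling(epochs / 5))
      cfg$seed <- seed
      fit <- trainModel(model, tcTrain, ds@design, cfg)
      pred <- predictModel(fit$model, ds@design, anchors = 0:(window - 1))
      pred@times <- as.numeric(0:(window - 1))
      pred0 <- baselineSubtractT0(pred)
      held <- setdiff(0:(window - 1), steps)
      hIdx <- match(held, 0:(window - 1))
      r <- .pearson(as.numeric(pred0@values[, hIdx, ]),
                    as.numeric(obs0@values[, hIdx, ]))
      out[[length(out) + 1]] <- data.frame(fraction = fractions[i],
                                           nAnchors = length(steps),
                                           seed = seed, r = r)
    }
  }
  do.call(rbind, out)
}

#' Zero-shot drug-count scaling protocol on synthetic data
#'
#' Leave-one-drug-out evaluation as a function of training-set size: for
#' each requested size, folds are drawn by sampling `n + 1` distinct
#' single-target synthetic drugs, training on the control plus `n` of them
#' and predicting the held-out drug zero-shot (its untrained drug-target
#' weight defaults to 1, so only prior connectivity and the trained
#' signaling representation are used). The score per fold is the pooled
#' control-subtracted Pearson correlation over sites and nonzero times.
#'
#' @param gt a [SyntheticGroundTruth-class] with sites assigned.
#' @param nDrugsGrid training-set sizes to evaluate.
#' @param nFolds folds sampled per size and seed.
#' @param epochs training epochs: a scalar, or one value per entry of
#'   `nDrugsGrid` (larger training sets see more samples per epoch, so fewer
#'   epochs reach the same optimizer-step budget).
#' @param seeds one replicate per seed.
#' @param times,L sampling grid and recurrent steps of the simulated data.
#' @param config base [trainingConfig()].
#' @return data.frame with columns `nDrugs`, `fold`, `seed`, `heldOut`, `r`.
#' @export
runDrugScalingProtocol <- function(gt, nDrugsGrid = c(5, 15), nFolds = 3,
                                   epochs = 200, seeds = 1:3,
                                   times = c(0, 1, 2, 3, 5, 8, 10, 15, 20, 50),
                                   L = 150, config = trainingConfig()) {
  pool <- names(gt@drugTargets)
  if (max(nDrugsGrid) + 1 > length(pool))
    stop("not enough targetable nodes for the requested training sizes")
  epochs <- rep(epochs, length.out = length(nDrugsGrid))
  out <- list()
  for (seed in seeds) {
    for (gi in seq_along(nDrugsGrid)) {
      n <- nDrugsGrid[gi]
      op <- .withSeed(1e4 * seed + n)
      folds <- lapply(seq_len(nFolds), function(j) sample(pool, n + 1))
      op()
      for (j in seq_len(nFolds)) {
        drugs <- folds[[j]]
        held <- drugs[n + 1]
        ds <- generateTimecourse(gt, drugs, times = times, L = L,
                                 seed = gt@seed + 100 * seed + j)
        trainSamples <- c("CTRL", setdiff(drugs, held))
        idx <- match(trainSamples, ds@design@sampleIds)
        tcTrain <- phosphoTimeCourse(
          ds@timecourse@values[, , idx, drop = FALSE], ds@timecourse@siteIds,
          ds@timecourse@times, trainSamples,
          ds@timecourse@mask[, , idx, drop = FALSE])
        designTrain <- ds@design[idx]
        designTrain@drugMatrix <- designTrain@drugMatrix[,
          setdiff(drugs, held), drop = FALSE]
        designTrain@drugTargets <- designTrain@drugTargets[setdiff(drugs, held)]
        model <- phosphoModel(gt@network, ds@assignment, designTrain,
                              times = times, L = L, seed = seed)
        cfg <- config
        cfg$epochs <- epochs[gi]
        cfg$restartPeriod <- max(1, ceiling(epochs[gi] / 5))
        cfg$seed <- seed * 1000 + j
        fit <- trainModel(model, tcTrain, designTrain, cfg)
        pred <- predictModel(fit$model, ds@design)
        r <- .zeroShotR(pred, ds@timecourse, held)
        out[[length(out) + 1]] <- data.frame(nDrugs = n, fold = j,
                                             seed = seed, heldOut = held,
                                             r = r)
      }
    }
  }
  do.call(rbind, out)
}

#' Held-out timepoint interpolation protocol
#'
#' Trains the model without the held-out timepoints, then infers them with
#' one of three anchor strategies: `"linear"` (model-free linear
#' interpolation of the observed data between flanking measured times),
#' `"reference_site"` (anchors for held-out times estimated from a dense
#' single-phosphosite series via [fitAnchorsFromReferenceSite()]) or
#' `"one_to_one"` (k-th timepoint of the full grid at recurrent step k).
#' Scores are per-timepoint Pearson correlations of time-zero-subtracted
#' values pooled over sites and samples. Holding out t = 0 (the baseline
#' anchor) is rejected.
#'
#' @param ds a [SyntheticDataset-class] (or any dataset bundle with
#'   design/timecourse/assignment and a network in `ds@groundTruth`).
#' @param heldOutTimes times (minutes) to hold out; subset of measured
#'   times, excluding 0.
#' @param strategy one of `"linear"`, `"reference_site"`, `"one_to_one"`.
#' @param refSite reference site id for `"reference_site"` (default: the
#'   site with the largest temporal variance in the control sample).
#' @param epochs,config training settings.
#' @param seed run seed.
#' @return data.frame with columns `time`, `strategy`, `r`.
#' @export
runInterpolationProtocol <- function(ds, heldOutTimes,
                                     strategy = c("linear", "reference_site",
                                                  "one_to_one"),
                                     refSite = NULL, epochs = 400,
                                     config = trainingConfig(), seed = 1) {
  strategy <- match.arg(strategy)
  tc <- ds@timecourse
  if (any(heldOutTimes == 0)) stop("holding out t = 0 is not allowed")
  if (!all(heldOutTimes %in% tc@times)) stop("held-out times not measured")
  allTimes <- tc@times
  trainTimes <- setdiff(allTimes, heldOutTimes)
  obs0 <- baselineSubtractT0(tc)
  hIdx <- match(heldOutTimes, allTimes)

  if (strategy == "linear") {
    r <- vapply(hIdx, function(ti) {
      lo <- max(which(allTimes %in% trainTimes & allTimes < allTimes[ti]))
      hi <- min(which(allTimes %in% trainTimes & allTimes > allTimes[ti]))
      w <- (allTimes[ti] - allTimes[lo]) / (allTimes[hi] - allTimes[lo])
      est <- (1 - w) * obs0@values[, lo, ] + w * obs0@values[, hi, ]
      .pearson(as.numeric(est), as.numeric(obs0@values[, ti, ]))
    }, numeric(1))
    return(data.frame(time = heldOutTimes, strategy = strategy, r = r))
  }

  net <- ds@groundTruth@network
  tcTrain <- subsetTimes(tc, trainTimes)
  model <- phosphoModel(net, ds@assignment, ds@design, times = trainTimes,
                        L = if (strategy == "one_to_one") max(150, length(allTimes))
                            else 150, seed = seed)
  if (strategy == "one_to_one")
    model <- fixAnchors(model, match(trainTimes, allTimes) - 1)
  cfg <- config
  cfg$epochs <- epochs
  cfg$restartPeriod <- max(1, ceiling(epochs / 5))
  cfg$seed <- seed
  fit <- trainModel(model, tcTrain, ds@design, cfg)

  trainedAnchors <- modelAnchors(fit$model)
  fullAnchors <- rep(NA_real_, length(allTimes))
  fullAnchors[match(trainTimes, allTimes)] <- trainedAnchors
  if (strategy == "one_to_one") {
    fullAnchors <- seq_along(allTimes) - 1
  } else {
    if (is.null(refSite)) {
      v <- apply(tc@values[, , 1], 1, stats::var)
      refSite <- tc@siteIds[which.max(v)]
    }
    predCtrl <- predictModel(fit$model, ds@design[1],
                             anchors = 0:(fit$model@nSteps - 1))
    refTraj <- predCtrl@values[match(refSite, predCtrl@siteIds), , 1]
    refMeas <- tc@values[match(refSite, tc@siteIds), , 1]
    fullAnchors <- fitAnchorsFromReferenceSite(refTraj, refMeas,
                                               fixed = fullAnchors)
  }
  pred <- predictModel(fit$model, ds@design, anchors = fullAnchors)
  pred@times <- allTimes
  pred0 <- baselineSubtractT0(pred)
  r <- vapply(hIdx, function(ti)
    .pearson(as.numeric(pred0@values[, ti, ]),
             as.numeric(obs0@values[, ti, ])), numeric(1))
  data.frame(time = heldOutTimes, strategy = strategy, r = r)
}

#' Prediction stability across random initializations
#'
#' Trains several models differing only in their initialization/run seed and
#' reports the coefficient of variation (sd/mean) of the raw predictions for
#' every (site, timepoint, sample) entry. Entries whose mean prediction is
#' near zero have an ill-defined CV and are reported as `NA`.
#'
#' @param network,assignment,design,timecourse the training problem.
#' @param nSeeds number of independently trained models (>= 2).
#' @param epochs,config training settings.
#' @param times,L model grid (defaults from the time course).
#' @param meanEps |mean| below which the CV is reported missing.
#' @return list with `cv` (numeric vector of CVs, NA where undefined) and
#'   `fracBelow` function(fraction threshold) giving the fraction of defined
#'   CVs below a threshold.
#' @export
# CV rule shared with seedStability: sd/|mean| per row of a predictions
# matrix (rows: site-sample-time entries, cols: seeds); NA when the mean is
# too close to zero for a meaningful ratio
.cvStats <- function(M, meanEps = 1e-3) {
  mu <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  ifelse(abs(mu) < meanEps, NA_real_, sdv / abs(mu))
}

seedStability <- function(network, assignment, design, timecourse,
                          nSeeds = 10, epochs = 200,
                          config = trainingConfig(), L = 150,
                          meanEps = 1e-3) {
  stopifnot(nSeeds >= 2)
  preds <- lapply(seq_len(nSeeds), function(s) {
    model <- phosphoModel(network, assignment, design,
                          times = timecourse@times, L = L, seed = s)
    cfg <- config
    cfg$epochs <- epochs
    cfg$restartPeriod <- max(1, ceiling(epochs / 5))
    cfg$seed <- s
    fit <- trainModel(model, timecourse, design, cfg)
    as.numeric(predictModel(fit$model, design)@values)
  })
  M <- do.call(cbind, preds)
  cv <- .cvStats(M, meanEps)
  list(cv = cv,
       fracBelow = function(thr) mean(cv[!is.na(cv)] < thr))
}

#' Infer kinase-substrate relations by in-silico inhibition
#'
#' For each kinase node, simulates its inhibition (the fixed -5 input on top
#' of the stimulated control) with the trained model and flags phosphosites
#' whose predicted control-subtracted change at the last timepoint falls at
#' or below `threshold`, restricted to sites whose assigned node is directly
#' connected to the kinase by one outgoing edge (the kinase's own sites are
#' excluded so signaling nodes are not misclassified as substrates; direct
#' connections only trade sensitivity for specificity). Candidates are
#' classified against a curated reference restricted to the model's
#' measured sites: `validated` (predicted and in the reference),
#' `predicted_only`, `database_only`. The three lists partition the
#' candidate set.
#'
#' @param model a trained [PhosphoModel-class].
#' @param kinases character vector of kinase node ids (must be in the
#'   network).
#' @param reference data.frame with columns `kinase`, `site`: the curated
#'   kinase-substrate pairs.
#' @param ligand,receptors the stimulation applied to both conditions
#'   (defaults to the model's first ligand and its trained receptors).
#' @param threshold predicted decrease at or below which a site counts as
#'   downregulated (default -0.5; reported in the output).
#' @return named list per kinase, each with `validated`, `predicted_only`
#'   and `database_only` site vectors; the threshold is attached as an
#'   attribute.
#' @export
inferKinaseSubstrates <- function(model, kinases, reference,
                                  ligand = NULL, receptors = NULL,
                                  threshold = -0.5) {
  net <- model@network
  for (k in kinases)
    if (!k %in% net@nodes) stop("kinase absent from network: ", k)
  stopifnot(all(c("kinase", "site") %in% names(reference)))
  if (is.null(ligand)) ligand <- model@ligands[1]
  if (is.null(receptors)) {
    nm <- names(model@params$ligandRaw)
    receptors <- sub("^.*\\|", "", nm[startsWith(nm, paste0(ligand, "|"))])
  }
  measured <- model@assignment@siteIds
  siteNode <- assignedNodes(model@assignment)
  A <- net@adjacency
  out <- lapply(kinases, function(kin) {
    design <- perturbationDesign(
      c("CTRL", "INHIB"),
      ligandMatrix = matrix(1, 2, 1, dimnames = list(NULL, ligand)),
      drugMatrix = matrix(c(0, 1), 2, 1, dimnames = list(NULL, "ksInhibitor")),
      drugTargets = list(ksInhibitor = kin),
      ligandReceptors = stats::setNames(list(receptors), ligand))
    pred <- predictModel(model, design)
    K <- length(pred@times)
    change <- pred@values[, K, 2] - pred@values[, K, 1]
    # one-edge neighborhood of the kinase (kin -> node), own node excluded
    direct <- net@nodes[A[, match(kin, net@nodes)] == 1]
    direct <- setdiff(direct, kin)
    eligible <- measured[siteNode %in% direct]
    predicted <- eligible[change[match(eligible, measured)] <= threshold]
    refSites <- intersect(reference$site[reference$kinase == kin], measured)
    list(validated = intersect(predicted, refSites),
         predicted_only = setdiff(predicted, refSites),
         database_only = setdiff(refSites, predicted))
  })
  names(out) <- kinases
  attr(out, "threshold") <- threshold
  out
}

#' Naive kinase-substrate inference from differential data alone
#'
#' The data-only comparator: flags sites whose observed absolute difference
#' between an inhibitor condition and the stimulated control passes a
#' threshold, and classifies them against the curated reference pairs of
#' the inhibitor's target kinase with the same scheme as
#' [inferKinaseSubstrates()].
#'
#' @param obsInhibitor,obsStimulated named numeric vectors of observed site
#'   intensities under the two conditions (names are site ids; shared sites
#'   are used).
#' @param reference data.frame with columns `kinase`, `site`.
#' @param targetKinase the inhibitor's target kinase node id.
#' @param threshold absolute difference at or above which a site is flagged.
#' @return list with `validated`, `predicted_only`, `database_only`;
#'   threshold attached as an attribute.
#' @export
naiveDEInference <- function(obsInhibitor, obsStimulated, reference,
                             targetKinase, threshold = 0.5) {
  shared <- intersect(names(obsInhibitor), names(obsStimulated))
  if (length(shared) == 0) stop("no shared sites between conditions")
  diff <- obsInhibitor[shared] - obsStimulated[shared]
  flagged <- shared[abs(diff) >= threshold]
  refSites <- intersect(reference$site[reference$kinase == targetKinase],
                        shared)
  out <- list(validated = intersect(flagged, refSites),
              predicted_only = setdiff(flagged, refSites),
              database_only = setdiff(refSites, flagged))
  attr(out, "threshold") <- threshold
  out
}
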