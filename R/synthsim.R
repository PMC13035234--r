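#' Sample a random signed directed signaling network
#'
#' Generates a synthetic scaffold emulating a curated signaling network: a
#' designated receptor node (default `EGFR`, stimulated by ligand `EGF` in
#' the simulated experiments) from which every node is reachable (each node
#' gets one upstream parent closer to the receptor, guaranteeing the
#' reachability that network pruning would otherwise enforce), plus extra
#' random directed edges that create convergence and feedback loops. Edge
#' signs are activating with probability `1 - pInhibit`.
#'
#' @param nNodes number of nodes.
#' @param avgDegree average out-degree (>= 1; 1 is the spanning tree alone).
#' @param pInhibit probability an edge is inhibiting.
#' @param receptor identifier for the receptor node.
#' @param seed RNG seed.
#' @return a [SignedNetwork-class].
#' @export
randomSignedNetwork <- function(nNodes, avgDegree = 2.5, pInhibit = 0.2,
                                receptor = "EGFR", seed = 1) {
  stopifnot(nNodes >= 2, avgDegree >= 1)
  op <- .withSeed(seed)
  on.exit(op())
  nodes <- c(receptor, sprintf("N%03d", seq_len(nNodes - 1)))
  # spanning structure: node i (> 1) receives an edge from an earlier node
  src <- vapply(2:nNodes, function(i) sample.int(i - 1, 1), integer(1))
  edges <- data.frame(source = nodes[src], target = nodes[2:nNodes])
  nExtra <- max(0, round(nNodes * (avgDegree - 1)))
  if (nExtra > 0) {
    es <- sample.int(nNodes, nExtra, replace = TRUE)
    et <- sample.int(nNodes, nExtra, replace = TRUE)
    keep <- es != et          # no self-loops in the synthetic scaffold
    edges <- rbind(edges, data.frame(source = nodes[es[keep]],
                                     target = nodes[et[keep]]))
  }
  key <- paste(edges$source, edges$target)
  edges <- edges[!duplicated(key), ]
  edges$sign <- ifelse(stats::runif(nrow(edges)) < pInhibit, -1, 1)
  signedNetwork(edges, nodes = nodes)
}

#' Sample a synthetic ground-truth signaling model
#'
#' Draws a generating parameterization on the network's support: weight
#' magnitudes log-uniform in `weightRange` carrying the curated signs, then
#' rescaled so the spectral radius of the magnitude matrix `|W|` equals
#' `spectralTarget` (< 1, contractive dynamics); biases are small Gaussian.
#' Each node's total incoming magnitude is balanced near one before the
#' rescaling, so cascades propagate without dying away. Every non-receptor
#' node with appreciable activity at the stimulated fixed point (>= 10% of
#' the maximal node activity) becomes a targetable synthetic drug
#' (`DRUG_<node>`), each inhibiting that single node with the fixed strong
#' negative input (-5); silent nodes are not offered as targets, as a drug
#' panel targets active signaling proteins.
#'
#' @param network a [SignedNetwork-class] (nonempty).
#' @param spectralTarget spectral radius of `|W|` after rescaling.
#' @param weightRange range of pre-rescaling weight magnitudes (log-uniform).
#' @param biasSd standard deviation of the node biases.
#' @param noiseSd replicate noise added to generated site intensities.
#' @param receptor the stimulated receptor node (excluded from drug targets).
#' @param seed RNG seed; the ground truth is deterministic given the seed.
#' @return a [SyntheticGroundTruth-class] (sites not yet assigned; see
#'   [assignSites()]).
#' @export
sampleGroundTruth <- function(network, spectralTarget = 0.9,
                              weightRange = c(0.1, 1), biasSd = 0.01,
                              noiseSd = 0.05, receptor = network@nodes[1],
                              seed = 1) {
  n <- length(network@nodes)
  if (n == 0 || nrow(network@edges) == 0) stop("empty network")
  op <- .withSeed(seed)
  on.exit(op())
  lw <- log(weightRange)
  mag <- matrix(exp(stats::runif(n * n, lw[1], lw[2])), n, n)
  mag <- mag * network@adjacency
  # balance each node's total incoming magnitude so signals neither explode
  # nor die away along deep cascades (kinase cascades propagate with gain
  # near one); relative input magnitudes stay log-uniform
  inSum <- rowSums(mag)
  gain <- exp(stats::runif(n, log(0.9), log(1.3)))
  mag <- mag * ifelse(inSum > 0, gain / inSum, 0)
  W <- network@signs * mag
  rho <- max(Mod(eigen(abs(W), only.values = TRUE)$values))
  if (rho > 0) W <- W * (spectralTarget / rho)
  dimnames(W) <- dimnames(network@adjacency)
  b <- stats::rnorm(n, sd = biasSd)
  # targetable synthetic drugs: nodes with appreciable activity under
  # receptor stimulation (a drug panel targets active signaling proteins;
  # inhibiting a silent node produces no measurable response)
  X <- matrix(0, n, 1, dimnames = list(network@nodes, "stim"))
  X[receptor, 1] <- 1
  H <- simulateTrajectory(W, b, X, L = 150)
  hFinal <- H[, 1, 150]
  active <- network@nodes[hFinal >= 0.1 * max(hFinal)]
  targets <- setdiff(active, receptor)
  if (length(targets) == 0) targets <- setdiff(network@nodes, receptor)
  drugTargets <- stats::setNames(as.list(targets), paste0("DRUG_", targets))
  methods::new("SyntheticGroundTruth", network = network, weights = W,
               bias = b,
               assignment = methods::new("SiteAssignment",
                                         siteIds = character(0),
                                         siteNodes = character(0)),
               siteScales = numeric(0), drugTargets = drugTargets,
               noiseSd = noiseSd, seed = seed,
               settings = list(spectralTarget = spectralTarget,
                               weightRange = weightRange, biasSd = biasSd,
                               receptor = receptor))
}

#' Assign synthetic phosphosites to network nodes
#'
#' Per-node site counts are drawn as `round(Exponential(mean = meanSites))`
#' (so some nodes carry no measured site), per-site scale factors
#' log-uniform in `scaleRange`; sites are named `NODE:S<k>`. The resulting
#' assignment and scales are stored in the returned ground truth and drive
#' the node-to-site transform of [generateTimecourse()].
#'
#' @param gt a [SyntheticGroundTruth-class].
#' @param meanSites mean of the exponential site-count distribution.
#' @param scaleRange range of per-site scale factors (log-uniform).
#' @param seed RNG seed.
#' @return the ground truth with `assignment` and `siteScales` filled.
#' @export
assignSites <- function(gt, meanSites = 2, scaleRange = c(0.25, 4),
                        seed = gt@seed + 1) {
  op <- .withSeed(seed)
  on.exit(op())
  nodes <- gt@network@nodes
  counts <- as.integer(round(stats::rexp(length(nodes), rate = 1 / meanSites)))
  if (sum(counts) == 0) stop("no sites generated")
  siteNodes <- rep(nodes, counts)
  siteIds <- unlist(lapply(seq_along(nodes), function(i)
    if (counts[i] > 0) paste0(nodes[i], ":S", seq_len(counts[i]))
    else character(0)))
  ls <- log(scaleRange)
  scales <- exp(stats::runif(length(siteIds), ls[1], ls[2]))
  gt@assignment <- siteAssignment(siteIds, siteNodes)
  gt@siteScales <- stats::setNames(scales, siteIds)
  gt@settings$meanSites <- meanSites
  gt@settings$scaleRange <- scaleRange
  gt
}

# node activity -> site intensity transform: positive part, rescaled by the
# node's cross-condition maximum, per-site scaled, log2-transformed.
.siteTransform <- function(hPos, nodeMax, scale) {
  # nodeMax/scale are per-site vectors recycling down the rows of the
  # sites x timepoints matrix; a node that never activates (max 0) yields
  # identically zero site values
  hn <- hPos / ifelse(nodeMax > 0, nodeMax, 1)
  log2(1 + scale * hn)
}

#' Generate a synthetic phosphoproteomic time-series dataset
#'
#' Simulates the ground-truth recurrent model for `L` steps under constant
#' ligand stimulation of the receptor: one unperturbed (stimulation-only)
#' control sample plus one sample per requested drug, each drug inhibiting
#' its single target node with the fixed -5 input. Node trajectories are
#' read at the generating time-map anchors (default the monotone concave map
#' `m = (L-1) * (t/max(t))^timeMapPower`, anchoring minute 0 to step 0 and
#' the last minute to the last step; pass explicit `anchors` to override,
#' e.g. `anchors = times` for step-resolved data), transformed to site
#' intensities (positive part, rescaled by the node's cross-condition
#' maximum, per-site scale, log2), and Gaussian replicate noise of sd
#' `gt@noiseSd` is added.
#'
#' @param gt a [SyntheticGroundTruth-class] with sites assigned.
#' @param drugs character vector of synthetic drug names (subset of
#'   `names(gt@drugTargets)`); `character(0)` for the control alone.
#' @param times sampling times in minutes (default the standard grid
#'   0,1,2,3,5,8,10,15,20,50).
#' @param L recurrent steps simulated (default 150).
#' @param timeMapPower exponent of the generating time map.
#' @param anchors optional explicit generating fractional steps (length of
#'   `times`).
#' @param noiseSd override of the replicate noise sd.
#' @param ligand name of the stimulating ligand.
#' @param seed RNG seed for the noise.
#' @return a [SyntheticDataset-class].
#' @export
generateTimecourse <- function(gt, drugs = character(0),
                               times = c(0, 1, 2, 3, 5, 8, 10, 15, 20, 50),
                               L = 150, timeMapPower = 0.6, anchors = NULL,
                               noiseSd = gt@noiseSd, ligand = "EGF",
                               seed = gt@seed + 2) {
  if (length(gt@assignment@siteIds) == 0)
    stop("assign sites first (see assignSites)")
  unknown <- setdiff(drugs, names(gt@drugTargets))
  if (length(unknown)) stop("unknown drug(s): ", paste(unknown, collapse = ", "))
  op <- .withSeed(seed)
  on.exit(op())
  receptor <- gt@settings$receptor
  sampleIds <- c("CTRL", drugs)
  B <- length(sampleIds)
  LM <- matrix(1, B, 1, dimnames = list(sampleIds, ligand))
  DM <- matrix(0, B, length(drugs), dimnames = list(sampleIds, drugs))
  if (length(drugs)) DM[cbind(1 + seq_along(drugs), seq_along(drugs))] <- 1
  design <- perturbationDesign(sampleIds, LM, DM,
                               drugTargets = gt@drugTargets[drugs],
                               ligandReceptors = stats::setNames(
                                 list(receptor), ligand))
  X <- buildInputs(design, gt@network)
  H <- simulateTrajectory(gt@weights, gt@bias, X, L = L)
  if (is.null(anchors)) {
    tmax <- max(times)
    anchors <- if (tmax > 0) (L - 1) * (times / tmax)^timeMapPower
               else rep(0, length(times))
  }
  stopifnot(length(anchors) == length(times),
            all(anchors >= 0), all(anchors <= L - 1))
  n <- dim(H)[1]; K <- length(anchors)
  hA <- array(0, c(n, B, K))
  f <- floor(anchors); dm <- anchors - f
  for (k in seq_len(K))
    hA[, , k] <- (1 - dm[k]) * H[, , f[k] + 1] +
      dm[k] * H[, , min(f[k] + 2, L)]
  hPos <- pmax(hA, 0)
  # rescale by the global cross-condition maximum: weakly activated nodes
  # yield weak site signals (per-site measurement gain is modeled separately
  # by the site scale factors; normalizing each node by its own maximum
  # would amplify numerically silent nodes into strong-looking but
  # unlearnable measurements)
  nodeMax <- rep(max(hPos), dim(hPos)[1])
  idx <- match(gt@assignment@siteNodes, gt@network@nodes)
  S <- length(idx)
  vals <- array(0, c(S, K, B))
  for (s in seq_len(B))
    vals[, , s] <- .siteTransform(hPos[idx, s, ], nodeMax[idx],
                                  gt@siteScales)
  if (noiseSd > 0)
    vals <- vals + array(stats::rnorm(length(vals), sd = noiseSd), dim(vals))
  tc <- phosphoTimeCourse(vals, gt@assignment@siteIds, times, sampleIds)
  methods::new("SyntheticDataset", design = design, timecourse = tc,
               assignment = gt@assignment, groundTruth = gt,
               metadata = list(seed = seed, noiseSd = noiseSd, L = L,
                               timeMapPower = timeMapPower,
                               generatingAnchors = anchors,
                               ligand = ligand, receptor = receptor,
                               groundTruthSeed = gt@seed))
}

#' Shuffle sample labels of a synthetic dataset
#'
#' Permutes the association between samples and their measured trajectories
#' while leaving the design unchanged (the shuffled-label control: a model
#' trained on such data should show negligible performance). The identity
#' permutation is excluded whenever more than one sample exists; with two
#' samples the result is the swap. The permutation is recorded in the
#' metadata.
#'
#' @param ds a [SyntheticDataset-class] with >= 2 samples.
#' @param seed RNG seed.
#' @return the dataset with permuted measurements.
#' @export
shuffleLabels <- function(ds, seed = 1) {
  B <- length(ds@timecourse@sampleIds)
  if (B < 2) stop("need at least 2 samples to shuffle labels")
  op <- .withSeed(seed)
  on.exit(op())
  repeat {
    perm <- sample.int(B)
    if (!all(perm == seq_len(B))) break
  }
  ds@timecourse@values <- ds@timecourse@values[, , perm, drop = FALSE]
  ds@timecourse@mask <- ds@timecourse@mask[, , perm, drop = FALSE]
  ds@metadata$labelPermutation <- perm
  ds
}

#' Write a synthetic dataset to a directory of plain-text tables
#'
#' Emits the external formats consumed elsewhere: `network.tsv` (edge
#' list), `phospho.tsv` (long format), `site_assignment.tsv`, `design.tsv`,
#' `drug_targets.tsv`, `ligand_receptors.tsv` and `metadata.json`.
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return (invisibly) the directory.
#' @export
writeSyntheticDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- ds@groundTruth
  if (!is.null(gt)) writeNetwork(gt@network, file.path(dir, "network.tsv"))
  writePhosphoTable(ds@timecourse, file.path(dir, "phospho.tsv"))
  writeSiteAssignment(ds@assignment, file.path(dir, "site_assignment.tsv"))
  writeDesign(ds@design, file.path(dir, "design.tsv"))
  writeDrugTargets(ds@design@drugTargets, file.path(dir, "drug_targets.tsv"))
  lr <- ds@design@ligandReceptors
  utils::write.table(data.frame(ligand = rep(names(lr), lengths(lr)),
                                receptor = unlist(lr, use.names = FALSE)),
                     file.path(dir, "ligand_receptors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds@metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic dataset written by [writeSyntheticDataset()]
#'
#' @param dir dataset directory.
#' @return a [SyntheticDataset-class] (without the ground-truth object).
#' @export
readSyntheticDataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  tc <- readPhosphoTable(file.path(dir, "phospho.tsv"))
  assignment <- readSiteAssignment(file.path(dir, "site_assignment.tsv"))
  targets <- readDrugTargets(file.path(dir, "drug_targets.tsv"))
  lr <- utils::read.delim(file.path(dir, "ligand_receptors.tsv"),
                          stringsAsFactors = FALSE)
  design <- readDesign(file.path(dir, "design.tsv"), drugTargets = targets,
                       ligandReceptors = split(lr$receptor, lr$ligand))
  # align sample order of the tensor with the design
  idx <- match(design@sampleIds, tc@sampleIds)
  tc <- phosphoTimeCourse(tc@values[, , idx, drop = FALSE], tc@siteIds,
                          tc@times, tc@sampleIds[idx],
                          tc@mask[, , idx, drop = FALSE])
  methods::new("SyntheticDataset", design = design, timecourse = tc,
               assignment = assignment, groundTruth = NULL,
               metadata = meta)
}
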