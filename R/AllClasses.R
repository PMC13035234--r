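#' @import methods
NULL

#' Signed directed prior-knowledge network
#'
#' Container for a signed, directed protein-interaction network: the
#' prior-knowledge scaffold that constrains which recurrent weights may be
#' nonzero. Rows of the adjacency matrix are targets and columns sources,
#' so `adjacency[j, i] == 1` iff an edge i -> j exists; the sign matrix holds
#' the curated mode of action (+1 activation, -1 inhibition) on the same
#' support.
#'
#' @slot nodes ordered character vector of unique node (protein) identifiers.
#' @slot edges data.frame with columns `source`, `target`, `sign`.
#' @slot adjacency nodes x nodes binary matrix (target x source).
#' @slot signs nodes x nodes matrix in \{-1, 0, +1\}, nonzero exactly on the
#'   adjacency support.
#' @exportClass SignedNetwork
setClass("SignedNetwork",
  slots = c(nodes = "character", edges = "data.frame",
            adjacency = "matrix", signs = "matrix"))

setValidity("SignedNetwork", function(object) {
  n <- length(object@nodes)
  if (anyDuplicated(object@nodes)) return("node identifiers must be unique")
  if (!all(dim(object@adjacency) == c(n, n))) return("adjacency dimension mismatch")
  if (!all(dim(object@signs) == c(n, n))) return("sign matrix dimension mismatch")
  if (!all(object@adjacency %in% c(0, 1))) return("adjacency must be binary")
  if (!all(object@signs %in% c(-1, 0, 1))) return("signs must be in {-1,0,1}")
  if (!identical(unname(object@signs != 0), unname(object@adjacency == 1)))
    return("sign matrix must be nonzero exactly where adjacency is 1")
  ed <- object@edges
  if (nrow(ed) > 0 &&
      !all(c(ed$source, ed$target) %in% object@nodes))
    return("edge endpoints must all be present in nodes")
  TRUE
})

#' Prior-knowledge network with trained interaction weights
#'
#' A [SignedNetwork-class] together with a real-valued weight matrix `W`
#' learned by training. While the prior mask is active, `W` is nonzero only
#' on the adjacency support; the fully connected no-prior variant sets
#' `maskActive = FALSE`.
#'
#' @slot network the underlying [SignedNetwork-class].
#' @slot weights nodes x nodes numeric matrix (target x source).
#' @slot maskActive logical; is the prior-knowledge support enforced?
#' @exportClass TrainedNetwork
setClass("TrainedNetwork",
  slots = c(network = "SignedNetwork", weights = "matrix",
            maskActive = "logical"))

setValidity("TrainedNetwork", function(object) {
  n <- length(object@network@nodes)
  if (!all(dim(object@weights) == c(n, n))) return("weight dimension mismatch")
  if (isTRUE(object@maskActive) &&
      any(object@weights[object@network@adjacency == 0] != 0))
    return("weights outside the prior-knowledge support must be zero")
  TRUE
})

#' Phosphosite-to-node assignment
#'
#' Maps each measured phosphosite (identifier `GENE:RESIDUEposition`, e.g.
#' `FOXO3:S7`) to exactly one signaling node; equivalent to the binary
#' node x site selection matrix with one-hot columns used by the phosphosite
#' mapping layer.
#'
#' @slot siteIds ordered character vector of phosphosite identifiers.
#' @slot siteNodes character vector, same length: the node carrying each site.
#' @exportClass SiteAssignment
setClass("SiteAssignment",
  slots = c(siteIds = "character", siteNodes = "character"))

setValidity("SiteAssignment", function(object) {
  if (length(object@siteIds) != length(object@siteNodes))
    return("siteIds and siteNodes must have equal length")
  if (anyDuplicated(object@siteIds)) return("site identifiers must be unique")
  TRUE
})

#' Perturbation design: ligand stimulations and drug applications
#'
#' Per-sample binary application matrices for ligands and drugs, plus the
#' prior-knowledge projection of each perturbation onto network nodes
#' (ligand -> receptor nodes, drug -> target nodes).
#'
#' @slot sampleIds character vector of sample identifiers.
#' @slot ligandMatrix samples x ligands binary matrix.
#' @slot drugMatrix samples x drugs binary matrix.
#' @slot drugTargets named list: drug -> character vector of target node ids.
#' @slot ligandReceptors named list: ligand -> character vector of receptor
#'   node ids.
#' @exportClass PerturbationDesign
setClass("PerturbationDesign",
  slots = c(sampleIds = "character", ligandMatrix = "matrix",
            drugMatrix = "matrix", drugTargets = "list",
            ligandReceptors = "list"))

setValidity("PerturbationDesign", function(object) {
  B <- length(object@sampleIds)
  if (nrow(object@ligandMatrix) != B) return("ligandMatrix rows != samples")
  if (nrow(object@drugMatrix) != B) return("drugMatrix rows != samples")
  if (ncol(object@drugMatrix) > 0 &&
      !all(colnames(object@drugMatrix) %in% names(object@drugTargets)))
    return("every drug column needs a drugTargets entry")
  if (ncol(object@ligandMatrix) > 0 &&
      !all(colnames(object@ligandMatrix) %in% names(object@ligandReceptors)))
    return("every ligand column needs a ligandReceptors entry")
  TRUE
})

#' Phosphoproteomic time course
#'
#' A sites x timepoints x samples intensity tensor with a missingness mask
#' and the real-valued experimental times (minutes).
#'
#' @slot values numeric array, sites x times x samples.
#' @slot mask logical array of the same shape; TRUE where observed.
#' @slot siteIds character, length = dim 1.
#' @slot times numeric sampling times in minutes, length = dim 2.
#' @slot sampleIds character, length = dim 3.
#' @exportClass PhosphoTimeCourse
setClass("PhosphoTimeCourse",
  slots = c(values = "array", mask = "array", siteIds = "character",
            times = "numeric", sampleIds = "character"))

setValidity("PhosphoTimeCourse", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3-d array")
  if (!identical(dim(object@mask), d)) return("mask shape mismatch")
  if (length(object@siteIds) != d[1]) return("siteIds length mismatch")
  if (length(object@times) != d[2]) return("times length mismatch")
  if (length(object@sampleIds) != d[3]) return("sampleIds length mismatch")
  if (is.unsorted(object@times)) return("times must be non-decreasing")
  TRUE
})

#' Composed signaling model
#'
#' All trainable parameters of the composed model (recurrent network ->
#' phosphosite mapping -> time mapping) together with the structures they are
#' tied to. Parameters live in the `params` list: `W` (masked recurrent
#' weights), `b` (node bias), `ligandRaw`/`drugRaw` (softplus-parameterized
#' nonnegative input weights, named `"perturbation|node"`), `E` (site x d
#' embeddings), `W1`, `b1`, `w2`, `b2` (shared MLP), `deltaRaw`, `uRaw`,
#' `alpha` (time map).
#'
#' @slot network [SignedNetwork-class] scaffold.
#' @slot assignment [SiteAssignment-class] restricted to mappable sites.
#' @slot ligands,drugs character vectors of perturbations the model knows.
#' @slot times numeric experimental times the time map is anchored to.
#' @slot nSteps total number of recurrent steps L.
#' @slot params named list of numeric parameter arrays (see above).
#' @slot settings named list: `leak`, `embedDim`, `hiddenWidth`,
#'   `timeMapVariant`, `maskActive`, `siteMapMode`, `fixedAnchors`.
#' @exportClass PhosphoModel
setClass("PhosphoModel",
  slots = c(network = "SignedNetwork", assignment = "SiteAssignment",
            ligands = "character", drugs = "character", times = "numeric",
            nSteps = "numeric", params = "list", settings = "list"))

#' Ground truth of a synthetic signaling experiment
#'
#' The generating model retained for parameter-recovery and self-consistency
#' tests: true signed weights and biases, the site assignment with per-site
#' scales, the drug -> single-target map, and the generation settings.
#'
#' @slot network [SignedNetwork-class].
#' @slot weights,bias true recurrent parameters.
#' @slot assignment [SiteAssignment-class] (empty until [assignSites()]).
#' @slot siteScales per-site positive scale factors.
#' @slot drugTargets named list: synthetic drug -> single target node.
#' @slot noiseSd replicate noise standard deviation.
#' @slot seed integer seed the ground truth was sampled under.
#' @slot settings list of generation parameters (spectral target, site-count
#'   mean, scale range, generating time-map exponent, ...).
#' @exportClass SyntheticGroundTruth
setClass("SyntheticGroundTruth",
  slots = c(network = "SignedNetwork", weights = "matrix", bias = "numeric",
            assignment = "SiteAssignment", siteScales = "numeric",
            drugTargets = "list", noiseSd = "numeric", seed = "numeric",
            settings = "list"))

#' Synthetic dataset bundle
#'
#' A simulated phosphoproteomic experiment: design, time course, site
#' assignment, and a reference to the generating ground truth plus metadata
#' (seeds, generating anchors, noise level).
#'
#' @slot design [PerturbationDesign-class].
#' @slot timecourse [PhosphoTimeCourse-class].
#' @slot assignment [SiteAssignment-class].
#' @slot groundTruth the [SyntheticGroundTruth-class] (or NULL when loaded
#'   from disk without it).
#' @slot metadata named list.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  slots = c(design = "PerturbationDesign", timecourse = "PhosphoTimeCourse",
            assignment = "SiteAssignment", groundTruth = "ANY",
            metadata = "list"))
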