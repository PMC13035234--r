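#' @describeIn accessors node identifiers of a network
setMethod("nodeIds", "SignedNetwork", function(x) x@nodes)

#' @describeIn accessors edge table (source, target, sign) of a network
setMethod("edgeTable", "SignedNetwork", function(x) x@edges)

#' @describeIn accessors binary target x source adjacency matrix
setMethod("adjacencyMatrix", "SignedNetwork", function(x) x@adjacency)

#' @describeIn accessors mode-of-action sign matrix
setMethod("signMatrix", "SignedNetwork", function(x) x@signs)

#' @describeIn accessors node identifiers of a trained network
setMethod("nodeIds", "TrainedNetwork", function(x) x@network@nodes)

#' @describeIn accessors trained weight matrix
setMethod("weightMatrix", "TrainedNetwork", function(x) x@weights)

#' @describeIn accessors underlying signed network of a trained network
setMethod("adjacencyMatrix", "TrainedNetwork", function(x) x@network@adjacency)

#' @describeIn accessors site identifiers of an assignment
setMethod("siteIds", "SiteAssignment", function(x) x@siteIds)

#' @describeIn accessors node assigned to each site
setMethod("assignedNodes", "SiteAssignment", function(x)
  stats::setNames(x@siteNodes, x@siteIds))

#' @describeIn accessors sample identifiers of a design
setMethod("sampleIds", "PerturbationDesign", function(x) x@sampleIds)

#' @describeIn accessors site identifiers of a time course
setMethod("siteIds", "PhosphoTimeCourse", function(x) x@siteIds)

#' @describeIn accessors sample identifiers of a time course
setMethod("sampleIds", "PhosphoTimeCourse", function(x) x@sampleIds)

#' @describeIn accessors sampling times (minutes) of a time course
setMethod("timePoints", "PhosphoTimeCourse", function(x) x@times)

#' @describeIn accessors sites x times x samples intensity array
setMethod("intensities", "PhosphoTimeCourse", function(x) x@values)

#' @describeIn accessors logical observation mask
setMethod("validMask", "PhosphoTimeCourse", function(x) x@mask)

#' @describeIn accessors ground truth of a synthetic dataset
setMethod("groundTruth", "SyntheticDataset", function(x) x@groundTruth)

#' @describeIn accessors generating weight matrix of a ground truth
setMethod("weightMatrix", "SyntheticGroundTruth", function(x) x@weights)

#' @describeIn accessors network of a ground truth
setMethod("nodeIds", "SyntheticGroundTruth", function(x) x@network@nodes)

setMethod("selectionMatrix", "SiteAssignment", function(x, network) {
  idx <- match(x@siteNodes, network@nodes)
  if (anyNA(idx))
    stop("site assignment refers to nodes absent from the network: ",
         paste(unique(x@siteNodes[is.na(idx)]), collapse = ", "))
  P <- matrix(0, length(network@nodes), length(x@siteIds),
              dimnames = list(network@nodes, x@siteIds))
  P[cbind(idx, seq_along(idx))] <- 1
  P
})

setMethod("show", "SignedNetwork", function(object) {
  ed <- object@edges
  nSelf <- if (nrow(ed)) sum(ed$source == ed$target) else 0L
  cat("SignedNetwork:", length(object@nodes), "nodes,", nrow(ed), "edges",
      sprintf("(%d activating, %d inhibiting", sum(ed$sign == 1),
              sum(ed$sign == -1)))
  if (nSelf > 0) cat(",", nSelf, "self-loops")
  cat(")\n")
})

setMethod("show", "TrainedNetwork", function(object) {
  cat("TrainedNetwork:", length(object@network@nodes), "nodes,",
      sum(object@weights != 0), "nonzero weights;",
      if (object@maskActive) "prior mask active" else "fully connected", "\n")
})

setMethod("show", "SiteAssignment", function(object) {
  cat("SiteAssignment:", length(object@siteIds), "sites on",
      length(unique(object@siteNodes)), "nodes\n")
})

setMethod("show", "PerturbationDesign", function(object) {
  cat("PerturbationDesign:", length(object@sampleIds), "samples,",
      ncol(object@ligandMatrix), "ligands,", ncol(object@drugMatrix),
      "drugs\n")
})

setMethod("show", "PhosphoTimeCourse", function(object) {
  d <- dim(object@values)
  cat("PhosphoTimeCourse:", d[1], "sites x", d[2], "timepoints x", d[3],
      "samples;", round(100 * mean(object@mask), 1), "% observed\n",
      " times (min):", paste(object@times, collapse = ", "), "\n")
})

setMethod("show", "PhosphoModel", function(object) {
  cat("PhosphoModel:", length(object@network@nodes), "nodes,",
      length(object@assignment@siteIds), "sites,",
      length(object@times), "timepoints, L =", object@nSteps, "\n",
      " site map:", object@settings$siteMapMode,
      "| prior mask:", if (isTRUE(object@settings$maskActive)) "active" else "off",
      "\n")
})

setMethod("show", "SyntheticGroundTruth", function(object) {
  cat("SyntheticGroundTruth:", length(object@network@nodes), "nodes,",
      length(object@assignment@siteIds), "sites,",
      length(object@drugTargets), "drugs; seed", object@seed, "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset\n")
  show(object@design)
  show(object@timecourse)
})
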