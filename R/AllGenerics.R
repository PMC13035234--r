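#' @title Accessor generics
#' @description Accessors for the core data containers; use these instead of
#'   reaching into slots.
#' @param x an object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setGeneric("signMatrix", function(x) standardGeneric("signMatrix"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname accessors
#' @export
setGeneric("assignedNodes", function(x) standardGeneric("assignedNodes"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Selection matrix of a site assignment
#'
#' Builds the binary node x site matrix P with one-hot columns realizing the
#' site -> node map against a given network's node ordering.
#'
#' @param x a [SiteAssignment-class].
#' @param network a [SignedNetwork-class] supplying the node order.
#' @return numeric matrix, nodes x sites.
#' @export
setGeneric("selectionMatrix", function(x, network) standardGeneric("selectionMatrix"))
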