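#' Accessors for the core classes
#'
#' Slot access goes through these accessors; the slot layout is not part of
#' the API.
#'
#' @param x an `ErrorModel`, `GenotypeArray`, `LineageTree` or `RfModel`
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("errorParams", function(x) standardGeneric("errorParams"))
#' @rdname accessors
#' @export
setMethod("errorParams", "ErrorModel", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("arrayStates", function(x) standardGeneric("arrayStates"))

#' @rdname accessors
#' @export
setMethod("arrayStates", "GenotypeArray", function(x) {
  st <- x@state
  out <- array(CALL_STATES[st], dim = dim(st), dimnames = dimnames(st))
  out
})

#' @rdname accessors
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))
#' @rdname accessors
#' @export
setMethod("altCounts", "GenotypeArray", function(x) x@altCount)

#' @rdname accessors
#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))
#' @rdname accessors
#' @export
setMethod("refCounts", "GenotypeArray", function(x) x@refCount)

#' @rdname accessors
#' @export
setGeneric("cellVaf", function(x) standardGeneric("cellVaf"))
#' @rdname accessors
#' @export
setMethod("cellVaf", "GenotypeArray", function(x) x@vafArr)

#' @rdname accessors
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))
#' @rdname accessors
#' @export
setMethod("siteInfo", "GenotypeArray", function(x) x@siteInfo)

#' @rdname accessors
#' @export
setGeneric("arraySites", function(x) standardGeneric("arraySites"))
#' @rdname accessors
#' @export
setMethod("arraySites", "GenotypeArray", function(x) dimnames(x@state)[[1L]])

#' @rdname accessors
#' @export
setGeneric("arrayTissues", function(x) standardGeneric("arrayTissues"))
#' @rdname accessors
#' @export
setMethod("arrayTissues", "GenotypeArray", function(x) dimnames(x@state)[[2L]])

#' @rdname accessors
#' @export
setGeneric("arrayIndividuals", function(x) standardGeneric("arrayIndividuals"))
#' @rdname accessors
#' @export
setMethod("arrayIndividuals", "GenotypeArray",
          function(x) dimnames(x@state)[[3L]])

#' @rdname accessors
#' @export
setGeneric("treeLeaves", function(x) standardGeneric("treeLeaves"))
#' @rdname accessors
#' @export
setMethod("treeLeaves", "LineageTree", function(x) {
  nodes <- c(x@root, names(x@parent))
  setdiff(nodes, unique(x@parent))
})

#' @rdname accessors
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))
#' @rdname accessors
#' @export
setMethod("treeNodes", "LineageTree",
          function(x) c(x@root, names(x@parent)))

#' @rdname accessors
#' @export
setGeneric("treeRoot", function(x) standardGeneric("treeRoot"))
#' @rdname accessors
#' @export
setMethod("treeRoot", "LineageTree", function(x) x@root)

#' @rdname accessors
#' @export
setGeneric("tissueLeaf", function(x) standardGeneric("tissueLeaf"))
#' @rdname accessors
#' @export
setMethod("tissueLeaf", "LineageTree", function(x) x@tissueMap)

#' @rdname accessors
#' @export
setGeneric("dualOriginLeaves", function(x) standardGeneric("dualOriginLeaves"))
#' @rdname accessors
#' @export
setMethod("dualOriginLeaves", "LineageTree", function(x) x@dualOriginLeaves)

#' @rdname accessors
#' @export
setGeneric("clonalExpansionLeaves",
           function(x) standardGeneric("clonalExpansionLeaves"))
#' @rdname accessors
#' @export
setMethod("clonalExpansionLeaves", "LineageTree",
          function(x) x@clonalExpansionLeaves)

#' @rdname accessors
#' @export
setGeneric("rfThreshold", function(x) standardGeneric("rfThreshold"))
#' @rdname accessors
#' @export
setMethod("rfThreshold", "RfModel", function(x) x@threshold)

#' @rdname accessors
#' @export
setGeneric("rfMetadata", function(x) standardGeneric("rfMetadata"))
#' @rdname accessors
#' @export
setMethod("rfMetadata", "RfModel", function(x) x@metadata)
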