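#' @title Accessor generics
#' @description Small accessor generics for the cluster data model; slot
#'   access from user code is discouraged.
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))

#' @rdname accessors
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("orfs", function(x) standardGeneric("orfs"))

#' @rdname accessors
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))

#' @rdname accessors
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))

#' @rdname accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))

#' @rdname accessors
#' @export
setGeneric("units", function(x) standardGeneric("units"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' Count assembly-line modules of a cluster
#'
#' Counts loading and extension modules over all ORFs of the cluster.
#' Standalone (trans-acting) pieces and lone domains are not counted.
#'
#' @param x a GeneCluster (or OrfArchitecture).
#' @return a non-negative integer.
#' @examples
#' cl <- demoCluster("C/A_ser_/T-C/A_pro_/T-Te")
#' countModules(cl)  # 2
#' @export
setGeneric("countModules", function(x) standardGeneric("countModules"))

#' @rdname accessors
#' @export
setGeneric("alignmentPairs", function(x) standardGeneric("alignmentPairs"))

#' @rdname accessors
#' @export
setGeneric("isOrtholog", function(x) standardGeneric("isOrtholog"))
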