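#' @rdname adjacency
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname nodeTable
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname nNodes
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname binarize
#' @export
setGeneric("binarize", function(x) standardGeneric("binarize"))

#' @rdname dropRegions
#' @export
setGeneric("dropRegions", function(x, labels) standardGeneric("dropRegions"))

#' @rdname edgeDensity
#' @export
setGeneric("edgeDensity", function(x) standardGeneric("edgeDensity"))

#' @rdname members
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname thresholds
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
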