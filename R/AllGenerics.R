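#' @rdname timeWeights
#' @export
setGeneric("timeWeights", function(grid, ...) standardGeneric("timeWeights"))

#' @rdname deUnion
#' @export
setGeneric("deUnion", function(object, ...) standardGeneric("deUnion"))

#' @rdname comparisonMatrix
#' @export
setGeneric("comparisonMatrix",
           function(object, ...) standardGeneric("comparisonMatrix"))

#' @rdname clusterReport
#' @export
setGeneric("clusterReport",
           function(model, ...) standardGeneric("clusterReport"))

#' @rdname classifyModel
#' @export
setGeneric("classifyModel",
           function(model, grid, ...) standardGeneric("classifyModel"))

#' @rdname timeGrid
#' @export
setGeneric("timeGrid", function(object, ...) standardGeneric("timeGrid"))
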