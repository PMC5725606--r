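#' @rdname abundances
#' @export
setGeneric("abundances", function(x, ...) standardGeneric("abundances"))

#' @rdname sampleSupports
#' @export
setGeneric("sampleSupports", function(x, ...) standardGeneric("sampleSupports"))

#' @rdname zeroTol
#' @export
setGeneric("zeroTol", function(x) standardGeneric("zeroTol"))

#' @rdname averageReplicates
#' @export
setGeneric("averageReplicates", function(x, ...) standardGeneric("averageReplicates"))

#' @rdname signMatrix
#' @export
setGeneric("signMatrix", function(x) standardGeneric("signMatrix"))

#' @rdname confidence
#' @export
setGeneric("confidence", function(x) standardGeneric("confidence"))

#' @rdname interactionMatrix
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @rdname growthRates
#' @export
setGeneric("growthRates", function(x) standardGeneric("growthRates"))

#' @rdname rowDiagnostics
#' @export
setGeneric("rowDiagnostics", function(x) standardGeneric("rowDiagnostics"))

#' @rdname steadyState
#' @export
setGeneric("steadyState", function(model, support, ...) standardGeneric("steadyState"))

#' @rdname jacobianSignTruth
#' @export
setGeneric("jacobianSignTruth", function(model) standardGeneric("jacobianSignTruth"))
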