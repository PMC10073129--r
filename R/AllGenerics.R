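#' @include AllGenerics.R
NULL

#' Accessor generics for nanofp containers
#'
#' Small accessor generics used across the package's S4 containers.
#' Use these instead of reaching into slots with `@`.
#'
#' @param object a nanofp S4 object.
#' @return The corresponding slot value.
#' @name nanofp-accessors
NULL

#' @rdname nanofp-accessors
#' @export
setGeneric("traceCurrent", function(object) standardGeneric("traceCurrent"))

#' @rdname nanofp-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname nanofp-accessors
#' @export
setGeneric("appliedVoltage", function(object) standardGeneric("appliedVoltage"))

#' @rdname nanofp-accessors
#' @export
setGeneric("filterState", function(object) standardGeneric("filterState"))

#' @rdname nanofp-accessors
#' @export
setGeneric("landscapeGrid", function(object) standardGeneric("landscapeGrid"))

#' @rdname nanofp-accessors
#' @export
setGeneric("landscapeEnergy", function(object) standardGeneric("landscapeEnergy"))

#' @rdname nanofp-accessors
#' @export
setGeneric("psdFrequencies", function(object) standardGeneric("psdFrequencies"))

#' @rdname nanofp-accessors
#' @export
setGeneric("psdValues", function(object) standardGeneric("psdValues"))

#' @rdname nanofp-accessors
#' @export
setGeneric("titrationTable", function(object) standardGeneric("titrationTable"))

#' @rdname nanofp-accessors
#' @export
setGeneric("levelResiduals", function(object) standardGeneric("levelResiduals"))

#' @rdname nanofp-accessors
#' @export
setGeneric("levelOccupancies", function(object) standardGeneric("levelOccupancies"))
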