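#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("monomer", function(x) standardGeneric("monomer"))

#' @rdname accessors
#' @export
setGeneric("polymer", function(x) standardGeneric("polymer"))

#' @rdname accessors
#' @export
setGeneric("filaments", function(x) standardGeneric("filaments"))

#' @rdname accessors
#' @export
setGeneric("kineticParams", function(x) standardGeneric("kineticParams"))

#' @rdname accessors
#' @export
setGeneric("actinConc", function(x) standardGeneric("actinConc"))

#' @rdname accessors
#' @export
setGeneric("ccEstimate", function(x) standardGeneric("ccEstimate"))

#' @rdname accessors
#' @export
setGeneric("ccInterval", function(x) standardGeneric("ccInterval"))

#' @rdname accessors
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("hasPeriodicity", function(x) standardGeneric("hasPeriodicity"))
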