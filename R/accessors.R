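#' Accessors for pevkactin data objects
#'
#' Small accessor family: \code{traceTime} and \code{intensity} read the
#' time/intensity vectors of a \code{FluorescenceTrace} (and
#' \code{actinConc}/\code{intensity} those of a \code{SteadyStateSeries});
#' \code{monomer}, \code{polymer}, \code{filaments} and
#' \code{kineticParams} read a \code{KineticState}; \code{ccEstimate} and
#' \code{ccInterval} read a \code{CcFit}; \code{heights}, \code{pixelSize},
#' \code{peaks} and \code{hasPeriodicity} read the imaging classes.
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases traceTime intensity condition monomer polymer filaments
#'   kineticParams actinConc ccEstimate ccInterval heights pixelSize
#'   peaks hasPeriodicity
NULL

#' @rdname accessors
setMethod("traceTime", "FluorescenceTrace", function(x) x@time)

#' @rdname accessors
setMethod("traceTime", "KineticState", function(x) x@time)

#' @rdname accessors
setMethod("intensity", "FluorescenceTrace", function(x) x@intensity)

#' @rdname accessors
setMethod("intensity", "SteadyStateSeries", function(x) x@intensity)

#' @rdname accessors
setMethod("condition", "FluorescenceTrace", function(x) x@condition)

#' @rdname accessors
setMethod("condition", "SteadyStateSeries", function(x) x@condition)

#' @rdname accessors
setMethod("monomer", "KineticState", function(x) x@monomer)

#' @rdname accessors
setMethod("polymer", "KineticState", function(x) x@polymer)

#' @rdname accessors
setMethod("filaments", "KineticState", function(x) x@filaments)

#' @rdname accessors
setMethod("kineticParams", "KineticState", function(x) x@params)

#' @rdname accessors
setMethod("actinConc", "SteadyStateSeries", function(x) x@actinConc)

#' @rdname accessors
setMethod("ccEstimate", "CcFit", function(x) x@cc)

#' @rdname accessors
setMethod("ccInterval", "CcFit", function(x) x@ccCi)

#' @rdname accessors
setMethod("heights", "HeightImage", function(x) x@heights)

#' @rdname accessors
setMethod("pixelSize", "HeightImage", function(x) x@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "AmplitudeSpectrum", function(x) x@pixelSize)

#' @rdname accessors
setMethod("peaks", "PeriodicityResult", function(x) x@peaks)

#' @rdname accessors
setMethod("hasPeriodicity", "PeriodicityResult", function(x) x@hasPeriodicity)
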