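#' @import methods
NULL

.isScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
.isCount <- function(x) .isScalar(x) && abs(x - round(x)) < 1e-8

#' Illumination schedule of a fluorescence measurement
#'
#' Describes when the sample is exposed to excitation light: either
#' continuously, or intermittently in measurement windows of length
#' \code{window} seconds repeated every \code{period} seconds (the first
#' window opening at t = 0).  Intermittent illumination is the standard
#' mitigation for pyrene photobleaching in long steady-state assays.
#'
#' @slot mode \code{"continuous"} or \code{"intermittent"}.
#' @slot window measurement-window length in seconds (intermittent only).
#' @slot period window repeat period in seconds (intermittent only).
#' @name IlluminationSchedule-class
#' @exportClass IlluminationSchedule
setClass("IlluminationSchedule",
    representation(mode = "character", window = "numeric", period = "numeric"),
    prototype(mode = "continuous", window = NA_real_, period = NA_real_))

setValidity("IlluminationSchedule", function(object) {
    if (length(object@mode) != 1L ||
        !object@mode %in% c("continuous", "intermittent"))
        return("mode must be 'continuous' or 'intermittent'")
    if (object@mode == "intermittent") {
        if (!.isScalar(object@window) || !.isScalar(object@period))
            return("intermittent schedule needs numeric window and period")
        if (!(object@period > object@window && object@window > 0))
            return("need period > window > 0")
    }
    TRUE
})

#' Rate constants and composition of a polymerization run
#'
#' Parameters of the Oosawa-type nucleation-elongation scheme used by
#' \code{\link{simulatePolymerization}}: spontaneous nucleation of nuclei of
#' \code{nucleusSize} monomers, nucleator (PEVK)-mediated seeding of order
#' \code{seedOrder} in monomer, and reversible barbed-end elongation with the
#' critical concentration \code{kMinus/kPlus}.
#'
#' @slot kPlus elongation rate constant (per uM per s).
#' @slot kMinus depolymerization rate constant (per s).
#' @slot kNuc spontaneous nucleation rate constant
#'   (per uM^(nucleusSize - 1) per s).
#' @slot nucleusSize monomers per spontaneous nucleus (integer >= 2).
#' @slot kSeed nucleator-mediated seeding rate constant
#'   (per nM nucleator per uM^seedOrder per s).
#' @slot seedOrder monomer order of seeded nucleation (integer >= 1).
#' @slot nucleatorConc nucleator concentration (nM).
#' @slot actinTotal total actin (uM).
#' @slot labeledFraction fraction of pyrene-labeled actin in [0, 1].
#' @name KineticParams-class
#' @exportClass KineticParams
setClass("KineticParams",
    representation(kPlus = "numeric", kMinus = "numeric", kNuc = "numeric",
        nucleusSize = "numeric", kSeed = "numeric", seedOrder = "numeric",
        nucleatorConc = "numeric", actinTotal = "numeric",
        labeledFraction = "numeric"))

setValidity("KineticParams", function(object) {
    for (nm in c("kPlus", "kMinus", "kNuc", "kSeed", "nucleatorConc",
                 "actinTotal", "labeledFraction")) {
        v <- slot(object, nm)
        if (!.isScalar(v) || v < 0)
            return(sprintf("%s must be a single non-negative number", nm))
    }
    if (!.isCount(object@nucleusSize) || object@nucleusSize < 2)
        return("nucleusSize must be an integer >= 2")
    if (!.isCount(object@seedOrder) || object@seedOrder < 1)
        return("seedOrder must be an integer >= 1")
    if (object@labeledFraction > 1)
        return("labeledFraction must lie in [0, 1]")
    TRUE
})

#' Deterministic trajectory of a polymerization run
#'
#' Ground truth produced by \code{\link{simulatePolymerization}}: free
#' monomer, polymerized actin and filament number concentration on a time
#' grid.  Monomer and polymer always sum to the total actin (mass
#' conservation is built into the integration).
#'
#' @slot time time grid (s), strictly increasing from 0.
#' @slot monomer free G-actin (uM).
#' @slot polymer F-actin, i.e. polymerized monomer (uM).
#' @slot filaments filament number concentration (uM of filaments).
#' @slot params the \code{KineticParams} the run was generated from (with
#'   \code{nucleatorConc} as at t = 0; later additions live in the events).
#' @name KineticState-class
#' @exportClass KineticState
setClass("KineticState",
    representation(time = "numeric", monomer = "numeric",
        polymer = "numeric", filaments = "numeric",
        params = "KineticParams"))

setValidity("KineticState", function(object) {
    n <- length(object@time)
    if (length(object@monomer) != n || length(object@polymer) != n ||
        length(object@filaments) != n)
        return("time, monomer, polymer and filaments must share a length")
    if (n > 1 && any(diff(object@time) <= 0))
        return("time must be strictly increasing")
    tol <- 1e-6
    if (any(object@monomer < -tol) || any(object@polymer < -tol) ||
        any(object@filaments < -tol))
        return("concentrations must be non-negative")
    if (any(abs(object@monomer + object@polymer -
                object@params@actinTotal) > 1e-6 * (1 + object@params@actinTotal)))
        return("mass conservation violated: monomer + polymer != actinTotal")
    TRUE
})

#' Observation model for pyrene fluorescence
#'
#' Maps polymerized labeled actin to measured intensity:
#' \code{F(t) = baseline + gain * labeledFraction * polymer(t) *
#' exp(-kBleach * E(t)) + noise}, where \code{E(t)} is the cumulative
#' illuminated exposure under the \code{schedule}.
#'
#' @slot gain intensity units per uM labeled F-actin (> 0).
#' @slot baseline intensity units.
#' @slot kBleach photobleaching rate per second of illuminated exposure.
#' @slot noiseSd Gaussian noise standard deviation (intensity units).
#' @slot schedule an \code{\link{IlluminationSchedule-class}} object.
#' @slot seed RNG seed for the noise draw (\code{NA} = leave RNG alone).
#' @name ObservationParams-class
#' @exportClass ObservationParams
setClass("ObservationParams",
    representation(gain = "numeric", baseline = "numeric",
        kBleach = "numeric", noiseSd = "numeric",
        schedule = "IlluminationSchedule", seed = "numeric"))

setValidity("ObservationParams", function(object) {
    if (!.isScalar(object@gain) || object@gain <= 0)
        return("gain must be > 0")
    if (!.isScalar(object@baseline))
        return("baseline must be a single number")
    if (!.isScalar(object@kBleach) || object@kBleach < 0)
        return("kBleach must be >= 0")
    if (!.isScalar(object@noiseSd) || object@noiseSd < 0)
        return("noiseSd must be >= 0")
    if (length(object@seed) != 1L)
        return("seed must be a single number or NA")
    TRUE
})

#' A measured (or simulated) fluorescence time trace
#'
#' @slot time sample times (s), strictly increasing.
#' @slot intensity fluorescence intensity (arbitrary units).
#' @slot condition free-text condition label.
#' @slot schedule the illumination schedule the trace was acquired under.
#' @name FluorescenceTrace-class
#' @exportClass FluorescenceTrace
setClass("FluorescenceTrace",
    representation(time = "numeric", intensity = "numeric",
        condition = "character", schedule = "IlluminationSchedule"))

setValidity("FluorescenceTrace", function(object) {
    if (length(object@time) != length(object@intensity))
        return("time and intensity must have equal length")
    if (length(object@time) > 1 && any(diff(object@time) <= 0))
        return("time must be strictly increasing")
    if (length(object@condition) != 1L)
        return("condition must be a single string")
    TRUE
})

#' Summary metrics of one polymerization trace
#'
#' The four quantities used to characterize a pyrene trace: the initial
#' assembly rate (slope over the early window), the half-maximal (log-phase)
#' rate, the peak intensity, and the time at which the peak is first
#' attained.  Slopes carry the standard error of the linear fit.
#'
#' @slot initialRate,initialRateSe intensity per s.
#' @slot halfmaxRate,halfmaxRateSe intensity per s.
#' @slot peakIntensity intensity units (on the smoothed trace).
#' @slot timeToPeak s.
#' @slot windows named list of the (start, end) windows actually fitted.
#' @name TraceMetrics-class
#' @exportClass TraceMetrics
setClass("TraceMetrics",
    representation(initialRate = "numeric", initialRateSe = "numeric",
        halfmaxRate = "numeric", halfmaxRateSe = "numeric",
        peakIntensity = "numeric", timeToPeak = "numeric",
        windows = "list"))

#' Steady-state intensity as a function of actin concentration
#'
#' One point per total actin concentration, measured after assembly has
#' reached steady state; the input to critical-concentration fitting.
#'
#' @slot actinConc total actin (uM), strictly increasing, length >= 3.
#' @slot intensity steady-state intensity (arbitrary units).
#' @slot condition condition label.
#' @name SteadyStateSeries-class
#' @exportClass SteadyStateSeries
setClass("SteadyStateSeries",
    representation(actinConc = "numeric", intensity = "numeric",
        condition = "character"))

setValidity("SteadyStateSeries", function(object) {
    n <- length(object@actinConc)
    if (n < 3L) return("need at least 3 concentrations")
    if (length(object@intensity) != n)
        return("actinConc and intensity must have equal length")
    if (any(object@actinConc < 0)) return("concentrations must be >= 0")
    if (any(diff(object@actinConc) <= 0))
        return("actinConc must be strictly increasing")
    if (length(object@condition) != 1L)
        return("condition must be a single string")
    TRUE
})

#' Critical-concentration fit
#'
#' Least-squares line through the above-threshold points of a
#' \code{\link{SteadyStateSeries-class}}, with the critical concentration as
#' its x-intercept and a residual-bootstrap confidence interval.  The
#' reported interval is widened, if necessary, to contain the point
#' estimate.
#'
#' @slot slope intensity per uM.
#' @slot intercept intensity units.
#' @slot cc critical concentration estimate (uM, >= 0).
#' @slot ccCi percentile bootstrap confidence interval (uM).
#' @slot nPointsUsed number of points entering the fit.
#' @slot bootstrapCc the bootstrap replicate estimates.
#' @slot condition condition label carried over from the series.
#' @name CcFit-class
#' @exportClass CcFit
setClass("CcFit",
    representation(slope = "numeric", intercept = "numeric", cc = "numeric",
        ccCi = "numeric", nPointsUsed = "numeric", bootstrapCc = "numeric",
        condition = "character"))

setValidity("CcFit", function(object) {
    if (object@cc < 0) return("cc must be >= 0")
    if (length(object@ccCi) != 2L) return("ccCi must have length 2")
    if (object@ccCi[1] > object@cc + 1e-12 ||
        object@ccCi[2] < object@cc - 1e-12)
        return("confidence interval must contain the point estimate")
    TRUE
})

#' Worm-like-chain geometry of a disordered protein domain
#'
#' Contour length, mean end-to-end distance and radius of gyration of an
#' ideal (conformationally relaxed) chain with the given persistence length.
#'
#' @slot nResidues number of amino acids.
#' @slot residueSpacing nm per residue (0.38 nm by default).
#' @slot persistenceLength nm.
#' @slot contourLength nm.
#' @slot endToEnd nm.
#' @slot radiusOfGyration nm.
#' @name ChainGeometry-class
#' @exportClass ChainGeometry
setClass("ChainGeometry",
    representation(nResidues = "numeric", residueSpacing = "numeric",
        persistenceLength = "numeric", contourLength = "numeric",
        endToEnd = "numeric", radiusOfGyration = "numeric"))

#' Sarcomere-lattice reach geometry
#'
#' Hexagonal double-lattice construction: the nearest thick-to-thin filament
#' distance is 2/3 of the d10 lattice spacing, and the reach margin compares
#' the chain's radius of gyration to that distance.
#'
#' @slot d10 thick-filament 1,0-plane lattice spacing (nm).
#' @slot thickThinDistance nearest thick-to-thin filament distance (nm).
#' @slot reachMargin radiusOfGyration - thickThinDistance (nm).
#' @slot radiusOfGyration nm.
#' @name LatticeGeometry-class
#' @exportClass LatticeGeometry
setClass("LatticeGeometry",
    representation(d10 = "numeric", thickThinDistance = "numeric",
        reachMargin = "numeric", radiusOfGyration = "numeric"))

#' Specification of a synthetic AFM height image
#'
#' Geometry of a rendered filament field: either a nematic paracrystal of
#' parallel Gaussian ridges at a fixed spacing, or radial asters of short
#' filaments emanating from focal globules.  Constructed with
#' \code{\link{paracrystalSpec}} or \code{\link{radialSpec}}.
#'
#' @slot sizePx image side in pixels (>= 64; images are square).
#' @slot pixelSize nm per pixel.
#' @slot mode \code{"paracrystal"} or \code{"radial"}.
#' @slot spacing inter-filament spacing (nm; paracrystal).
#' @slot filamentSigma Gaussian ridge cross-section sigma (nm).
#' @slot filamentHeight ridge height (nm).
#' @slot orientation filament axis angle from the image x axis (degrees;
#'   paracrystal).
#' @slot nAsters,filamentsPerAster radial-mode counts.
#' @slot filamentLength maximum filament length (nm; radial).
#' @slot globuleRadius,globuleHeight focal globule Gaussian sigma and
#'   height (nm; radial).
#' @slot minSeparation minimum distance between aster centers (nm).
#' @slot noiseSd Gaussian pixel noise sd (nm).
#' @slot seed RNG seed (\code{NA} = leave RNG alone).
#' @name ImageSpec-class
#' @exportClass ImageSpec
setClass("ImageSpec",
    representation(sizePx = "numeric", pixelSize = "numeric",
        mode = "character", spacing = "numeric", filamentSigma = "numeric",
        filamentHeight = "numeric", orientation = "numeric",
        nAsters = "numeric", filamentsPerAster = "numeric",
        filamentLength = "numeric", globuleRadius = "numeric",
        globuleHeight = "numeric", minSeparation = "numeric",
        noiseSd = "numeric", seed = "numeric"))

setValidity("ImageSpec", function(object) {
    if (!.isCount(object@sizePx) || object@sizePx < 64)
        return("sizePx must be an integer >= 64")
    if (!.isScalar(object@pixelSize) || object@pixelSize <= 0)
        return("pixelSize must be > 0")
    if (!object@mode %in% c("paracrystal", "radial"))
        return("mode must be 'paracrystal' or 'radial'")
    if (!.isScalar(object@noiseSd) || object@noiseSd < 0)
        return("noiseSd must be >= 0")
    if (object@filamentSigma <= 0 || object@filamentHeight <= 0)
        return("filament dimensions must be > 0")
    if (object@mode == "paracrystal") {
        if (!.isScalar(object@spacing) || object@spacing <= 2 * object@pixelSize)
            return("spacing must exceed 2 * pixelSize (Nyquist)")
    } else {
        if (!.isCount(object@nAsters) || object@nAsters < 0)
            return("nAsters must be a non-negative integer")
        if (!.isCount(object@filamentsPerAster) || object@filamentsPerAster < 0)
            return("filamentsPerAster must be a non-negative integer")
        if (object@filamentLength <= 0 || object@globuleRadius <= 0 ||
            object@globuleHeight <= 0 || object@minSeparation < 0)
            return("radial-mode physical sizes must be positive")
    }
    TRUE
})

#' A synthetic AFM height image
#'
#' @slot heights square matrix of heights (nm); rows index the image y axis.
#' @slot pixelSize nm per pixel.
#' @name HeightImage-class
#' @exportClass HeightImage
setClass("HeightImage",
    representation(heights = "matrix", pixelSize = "numeric"))

setValidity("HeightImage", function(object) {
    if (nrow(object@heights) != ncol(object@heights))
        return("heights must be square")
    if (!all(is.finite(object@heights)))
        return("heights must be finite")
    if (!.isScalar(object@pixelSize) || object@pixelSize <= 0)
        return("pixelSize must be > 0")
    TRUE
})

#' Centered 2D amplitude spectrum of a height image
#'
#' Amplitude of the discrete Fourier transform of the mean-subtracted,
#' Hann-windowed image.  \code{frequency} holds the per-axis frequency grid
#' in per-meter units, zero frequency centered.
#'
#' @slot amplitude square amplitude matrix (raw DFT magnitude).
#' @slot frequency frequency axis (per m), same for rows and columns.
#' @slot pixelSize nm per pixel of the source image.
#' @name AmplitudeSpectrum-class
#' @exportClass AmplitudeSpectrum
setClass("AmplitudeSpectrum",
    representation(amplitude = "matrix", frequency = "numeric",
        pixelSize = "numeric"))

#' Detected spatial periodicities of a directional spectrum
#'
#' @slot peaks data.frame with columns \code{spatialFrequency} (per m),
#'   \code{periodicity} (nm), \code{amplitude} and \code{prominence},
#'   sorted by amplitude (ties broken towards lower frequency).
#' @slot band the analysed spatial-frequency band (per m).
#' @slot hasPeriodicity \code{TRUE} if at least one prominent peak lies in
#'   the band.
#' @slot angle probe direction of the underlying directional spectrum
#'   (degrees), \code{NA} if not applicable.
#' @name PeriodicityResult-class
#' @exportClass PeriodicityResult
setClass("PeriodicityResult",
    representation(peaks = "data.frame", band = "numeric",
        hasPeriodicity = "logical", angle = "numeric"))

setValidity("PeriodicityResult", function(object) {
    if (length(object@band) != 2L || object@band[1] >= object@band[2])
        return("band must be (low, high) with low < high")
    need <- c("spatialFrequency", "periodicity", "amplitude", "prominence")
    if (!all(need %in% names(object@peaks)))
        return("peaks must have spatialFrequency, periodicity, amplitude, prominence")
    TRUE
})
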