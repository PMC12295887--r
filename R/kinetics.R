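#' Construct an illumination schedule
#'
#' @param mode \code{"continuous"} (default) or \code{"intermittent"}.
#' @param window measurement-window length in seconds (intermittent mode).
#' @param period window repeat period in seconds (intermittent mode).  The
#'   default intermittent schedule, a 10 s reading every 600 s, corresponds
#'   to one spectroscopic measurement every 10 minutes.
#' @return an \code{\link{IlluminationSchedule-class}} object.
#' @examples
#' IlluminationSchedule()
#' IlluminationSchedule("intermittent")
#' @export
IlluminationSchedule <- function(mode = c("continuous", "intermittent"),
                                 window = 10, period = 600) {
    mode <- match.arg(mode)
    if (mode == "continuous")
        new("IlluminationSchedule", mode = "continuous",
            window = NA_real_, period = NA_real_)
    else
        new("IlluminationSchedule", mode = "intermittent",
            window = as.numeric(window), period = as.numeric(period))
}

#' Construct kinetic parameters
#'
#' Defaults describe the standard assay condition: 4 uM total actin, 10%
#' pyrene labeled, barbed-end elongation constants kPlus = 11.6 per uM per s
#' and kMinus = 1.4 per s (critical concentration 0.121 uM), trimeric
#' spontaneous nuclei, and first-order seeded nucleation in monomer.  The
#' spontaneous and seeded nucleation constants are set so that 4 uM actin
#' self-assembles to steady state within a 2000 s assay window and tens of
#' nanomolar nucleator dominates the spontaneous pathway.
#'
#' @param kPlus,kMinus,kNuc,nucleusSize,kSeed,seedOrder,nucleatorConc
#'   see \code{\link{KineticParams-class}}.
#' @param actinTotal,labeledFraction see \code{\link{KineticParams-class}}.
#' @return a validated \code{KineticParams} object.
#' @examples
#' KineticParams(nucleatorConc = 32.5)
#' @export
KineticParams <- function(kPlus = 11.6, kMinus = 1.4, kNuc = 7.5e-9,
                          nucleusSize = 3, kSeed = 1e-7, seedOrder = 1,
                          nucleatorConc = 0, actinTotal = 4,
                          labeledFraction = 0.1) {
    new("KineticParams", kPlus = as.numeric(kPlus),
        kMinus = as.numeric(kMinus), kNuc = as.numeric(kNuc),
        nucleusSize = as.numeric(nucleusSize), kSeed = as.numeric(kSeed),
        seedOrder = as.numeric(seedOrder),
        nucleatorConc = as.numeric(nucleatorConc),
        actinTotal = as.numeric(actinTotal),
        labeledFraction = as.numeric(labeledFraction))
}

#' Construct observation parameters
#'
#' @param gain intensity units per uM labeled F-actin.
#' @param baseline intensity offset.
#' @param kBleach photobleaching rate per second of illuminated exposure.
#'   The default 1e-4 per s gives the slow post-peak intensity decay seen
#'   under continuous illumination.
#' @param noiseSd Gaussian noise sd (intensity units).
#' @param schedule an \code{\link{IlluminationSchedule}}.
#' @param seed RNG seed for the noise draw; \code{NA} leaves the RNG state
#'   alone.
#' @return a validated \code{ObservationParams} object.
#' @export
ObservationParams <- function(gain = 1000, baseline = 20, kBleach = 1e-4,
                              noiseSd = 0, schedule = IlluminationSchedule(),
                              seed = NA_real_) {
    new("ObservationParams", gain = as.numeric(gain),
        baseline = as.numeric(baseline), kBleach = as.numeric(kBleach),
        noiseSd = as.numeric(noiseSd), schedule = schedule,
        seed = as.numeric(seed))
}

#' Construct a fluorescence trace
#'
#' @param time sample times (s), strictly increasing.
#' @param intensity intensities (arbitrary units).
#' @param condition condition label.
#' @param schedule illumination schedule metadata.
#' @return a \code{\link{FluorescenceTrace-class}} object.
#' @export
FluorescenceTrace <- function(time, intensity, condition = "unnamed",
                              schedule = IlluminationSchedule()) {
    new("FluorescenceTrace", time = as.numeric(time),
        intensity = as.numeric(intensity),
        condition = as.character(condition), schedule = schedule)
}

#' Construct a steady-state series
#'
#' @param actinConc total actin concentrations (uM); sorted internally.
#' @param intensity steady-state intensities, matched to \code{actinConc}.
#' @param condition condition label.
#' @return a \code{\link{SteadyStateSeries-class}} object.
#' @export
SteadyStateSeries <- function(actinConc, intensity, condition = "unnamed") {
    o <- order(actinConc)
    new("SteadyStateSeries", actinConc = as.numeric(actinConc[o]),
        intensity = as.numeric(intensity[o]),
        condition = as.character(condition))
}

## Right-hand side of the nucleation-elongation scheme.  State is
## y = (cf, N, P): polymer mass, filament number concentration, nucleator.
## dN/dt  = kNuc * m^nc + kSeed * P * m^sc
## dcf/dt = nc * dN/dt + (kPlus * m - kMinus) * N
## with m = actinTotal - cf.  The nucleus mass is booked into cf at
## creation, so monomer + polymer is conserved by construction.  Net
## depolymerization is gated smoothly to zero as the polymer pool empties
## (scale 1e-6 uM, far below any observable signal), which keeps the
## below-critical-concentration fixed point at cf ~ 0 integrable.
.kineticRhs <- function(t, y, p) {
    cf <- y[[1]]; N <- y[[2]]; P <- y[[3]]
    m <- max(p$actinTotal - cf, 0)
    nuc <- p$kNuc * m^p$nC + p$kSeed * P * m^p$sC
    elong <- (p$kPlus * m - p$kMinus) * N
    if (elong < 0) elong <- elong * max(cf, 0) / (max(cf, 0) + 1e-6)
    list(c(p$nC * nuc + elong, nuc, 0))
}

.rhsList <- function(params) {
    list(kPlus = params@kPlus, kMinus = params@kMinus, kNuc = params@kNuc,
         nC = params@nucleusSize, kSeed = params@kSeed,
         sC = params@seedOrder, actinTotal = params@actinTotal)
}

.checkEvents <- function(events) {
    if (is.null(events)) return(NULL)
    if (!is.data.frame(events) ||
        !all(c("time", "deltaNucleator") %in% names(events)))
        stop("events must be a data.frame with columns time and deltaNucleator")
    if (any(events$time < 0) || any(events$deltaNucleator < 0))
        stop("event times and nucleator increments must be non-negative")
    if (is.unsorted(events$time))
        stop("events must be sorted by time")
    events
}

#' Simulate a nucleation-elongation polymerization run
#'
#' Integrates the Oosawa-type scheme (spontaneous nucleation of
#' \code{nucleusSize}-mers, nucleator-mediated seeding, reversible
#' elongation) with a stiff-safe solver (\code{deSolve::ode}, lsoda,
#' relative tolerance 1e-8, absolute 1e-10) and samples the solution on the
#' requested grid.  Nucleator additions are instantaneous concentration
#' steps; the nucleator acts catalytically (it is not consumed).
#'
#' @param params a \code{\link{KineticParams}} object.
#' @param times strictly increasing time grid (s) starting at 0.
#' @param events optional \code{data.frame(time, deltaNucleator)} of
#'   mid-run nucleator additions (nM), sorted by time.  Events at t = 0 are
#'   folded into the initial nucleator concentration.
#' @param filaments0 initial filament number concentration (uM), default 0.
#' @return a \code{\link{KineticState-class}} trajectory.
#' @examples
#' st <- simulatePolymerization(KineticParams(), seq(0, 2000, by = 5))
#' tail(monomer(st), 1)  # approaches kMinus/kPlus = 0.121 uM
#' @export
simulatePolymerization <- function(params, times, events = NULL,
                                   filaments0 = 0) {
    stopifnot(is(params, "KineticParams"))
    validObject(params)
    times <- as.numeric(times)
    if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
        stop("times must be a strictly increasing grid starting at 0")
    events <- .checkEvents(events)

    P0 <- params@nucleatorConc
    if (!is.null(events)) {
        at0 <- events$time <= times[1]
        P0 <- P0 + sum(events$deltaNucleator[at0])
        events <- events[!at0, , drop = FALSE]
        if (nrow(events) == 0) events <- NULL
    }

    y0 <- c(cf = 0, N = as.numeric(filaments0), P = P0)
    solveTimes <- times
    evArg <- NULL
    if (!is.null(events)) {
        keep <- events$time < max(times)
        events <- events[keep, , drop = FALSE]
        if (nrow(events) > 0) {
            evArg <- list(data = data.frame(
                var = "P", time = events$time,
                value = events$deltaNucleator, method = "add"))
            solveTimes <- sort(unique(c(times, events$time)))
        }
    }

    out <- deSolve::ode(y = y0, times = solveTimes, func = .kineticRhs,
                        parms = .rhsList(params), method = "lsoda",
                        rtol = 1e-8, atol = 1e-10, maxsteps = 50000,
                        events = evArg)
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1] < 0)
        stop("ODE integration failed to meet tolerance (istate = ",
             istate[1], ")")
    out <- out[match(times, out[, "time"]), , drop = FALSE]
    cf <- pmin(pmax(out[, "cf"], 0), params@actinTotal)
    new("KineticState", time = times, monomer = params@actinTotal - cf,
        polymer = cf, filaments = pmax(out[, "N"], 0), params = params)
}

## Cumulative illuminated exposure at times t and whether each time is
## illuminated.  Windows are [k*period, k*period + window].
.exposure <- function(t, schedule) {
    if (schedule@mode == "continuous")
        return(list(E = t, lit = rep(TRUE, length(t))))
    w <- schedule@window; p <- schedule@period
    phase <- t %% p
    list(E = floor(t / p) * w + pmin(phase, w),
         lit = phase <= w + 1e-9)
}

#' Observe a trajectory through the pyrene fluorescence model
#'
#' Applies \code{F(t) = baseline + gain * labeledFraction * polymer(t) *
#' exp(-kBleach * E(t)) + noise}, where \code{E(t)} is the cumulative
#' illuminated exposure under the schedule.  Under an intermittent schedule
#' only the illuminated grid times are emitted, and bleaching accrues only
#' during the measurement windows.
#'
#' @param state a \code{\link{KineticState-class}} trajectory.
#' @param obs an \code{\link{ObservationParams}} object.
#' @param condition condition label for the returned trace.
#' @return a \code{\link{FluorescenceTrace-class}} object.
#' @export
observeFluorescence <- function(state, obs, condition = "unnamed") {
    stopifnot(is(state, "KineticState"), is(obs, "ObservationParams"))
    validObject(obs)
    ex <- .exposure(state@time, obs@schedule)
    t <- state@time[ex$lit]
    E <- ex$E[ex$lit]
    cf <- state@polymer[ex$lit]
    if (length(t) == 0)
        stop("no illuminated sample times under this schedule")
    f <- obs@baseline + obs@gain * state@params@labeledFraction * cf *
        exp(-obs@kBleach * E)
    if (obs@noiseSd > 0) {
        if (!is.na(obs@seed)) set.seed(obs@seed)
        f <- f + stats::rnorm(length(f), sd = obs@noiseSd)
    }
    FluorescenceTrace(t, f, condition, obs@schedule)
}

.withSeed <- function(obs, seed) {
    obs@seed <- as.numeric(seed)
    obs
}

#' Simulate a nucleator dose series
#'
#' One trace per nucleator concentration, all other parameters shared.
#' Noise seeds are per-trace: \code{obs@seed + index - 1}.
#'
#' @param base a \code{\link{KineticParams}} object; its
#'   \code{nucleatorConc} is replaced per trace.
#' @param nucleatorConcs non-empty vector of nucleator concentrations (nM).
#' @param times simulation/observation grid (s) starting at 0.
#' @param obs an \code{\link{ObservationParams}} object.
#' @return list of \code{\link{FluorescenceTrace-class}} objects, one per
#'   concentration, labeled \code{"nucleator_<conc>_nM"}.
#' @export
simulateDoseSeries <- function(base, nucleatorConcs, times, obs) {
    if (length(nucleatorConcs) == 0)
        stop("nucleatorConcs must be non-empty")
    if (any(nucleatorConcs < 0))
        stop("nucleator concentrations must be >= 0")
    lapply(seq_along(nucleatorConcs), function(i) {
        p <- base
        p@nucleatorConc <- as.numeric(nucleatorConcs[i])
        st <- simulatePolymerization(p, times)
        o <- if (is.na(obs@seed)) obs else .withSeed(obs, obs@seed + i - 1)
        observeFluorescence(st, o,
            condition = sprintf("nucleator_%g_nM", nucleatorConcs[i]))
    })
}

## Time derivative of polymer mass at the end of a trajectory.
.finalRate <- function(state) {
    n <- length(state@time)
    y <- c(cf = state@polymer[n], N = state@filaments[n],
           P = state@params@nucleatorConc)
    .kineticRhs(state@time[n], y, .rhsList(state@params))[[1]][1]
}

#' Simulate a steady-state actin-concentration series
#'
#' Runs the simulator to \code{tEnd} for each total actin concentration and
#' records the steady-state intensity via \code{\link{observeFluorescence}}
#' (last illuminated sample).  Long runs are intended for an intermittent
#' schedule, which limits cumulative photobleaching.  Errors if any
#' concentration has not reached steady state, i.e. |d polymer/dt| at
#' \code{tEnd} exceeds \code{ssTol}.
#'
#' @param base a \code{\link{KineticParams}} object; \code{actinTotal} is
#'   replaced per condition.
#' @param actinConcs non-empty vector of total actin concentrations (uM).
#' @param tEnd final time (s); the assay's 8000 s span by default.
#' @param obs an \code{\link{ObservationParams}}; per-condition noise seeds
#'   are \code{obs@seed + index - 1}.
#' @param ssTol steady-state tolerance on |d polymer/dt| (uM per s).
#' @param nGrid number of grid points per run.
#' @return a \code{\link{SteadyStateSeries-class}} object.
#' @export
simulateCcSeries <- function(base, actinConcs, tEnd = 8000,
                             obs = ObservationParams(
                                 schedule = IlluminationSchedule("intermittent")),
                             ssTol = 1e-5, nGrid = 2001) {
    if (length(actinConcs) == 0) stop("actinConcs must be non-empty")
    if (any(actinConcs < 0)) stop("actin concentrations must be >= 0")
    actinConcs <- sort(as.numeric(actinConcs))
    times <- seq(0, tEnd, length.out = nGrid)
    ss <- vapply(seq_along(actinConcs), function(i) {
        p <- base
        p@actinTotal <- actinConcs[i]
        st <- simulatePolymerization(p, times)
        if (abs(.finalRate(st)) > ssTol)
            stop(sprintf(
                "steady state not reached at %g uM actin by t = %g s (|dcf/dt| = %.3g uM/s)",
                actinConcs[i], tEnd, abs(.finalRate(st))))
        o <- if (is.na(obs@seed)) obs else .withSeed(obs, obs@seed + i - 1)
        tr <- observeFluorescence(st, o)
        tr@intensity[length(tr@intensity)]
    }, numeric(1))
    SteadyStateSeries(actinConcs, ss, condition = sprintf(
        "nucleator_%g_nM", base@nucleatorConc))
}

#' Critical concentration implied by a parameter set
#'
#' The monomer fixed point of the elongation step, \code{kMinus/kPlus}.
#'
#' @param params a \code{\link{KineticParams}} object.
#' @return critical concentration (uM).
#' @export
criticalConcentration <- function(params) {
    stopifnot(is(params, "KineticParams"))
    if (params@kPlus <= 0) stop("kPlus must be > 0 for a finite Cc")
    params@kMinus / params@kPlus
}
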