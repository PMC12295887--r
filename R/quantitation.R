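## Least-squares slope with standard error, via stats::lm.
.fitSlope <- function(t, f) {
    if (length(t) < 3) stop("need at least 3 samples in the fit window")
    if (stats::var(t) == 0) stop("zero time variance in the fit window")
    fit <- stats::lm(f ~ t)
    # summary.lm warns on exact (zero-residual) fits; those are fine here
    co <- suppressWarnings(summary(fit))$coefficients
    list(slope = unname(co["t", "Estimate"]),
         se = unname(co["t", "Std. Error"]))
}

.windowIdx <- function(trace, window) {
    if (length(window) != 2 || window[1] >= window[2])
        stop("window must be (start, end) with start < end")
    which(trace@time >= window[1] & trace@time <= window[2])
}

#' Initial polymerization rate of a trace
#'
#' Ordinary least-squares slope of intensity versus time over the early
#' window (default 0-40 s), with the standard error of the linear fit.
#'
#' @param trace a \code{\link{FluorescenceTrace-class}} object.
#' @param window fit window \code{c(start, end)} in seconds.
#' @return list with \code{slope}, \code{se}, \code{window} and \code{n}.
#' @export
initialRate <- function(trace, window = c(0, 40)) {
    idx <- .windowIdx(trace, window)
    fit <- .fitSlope(trace@time[idx], trace@intensity[idx])
    c(fit, list(window = as.numeric(window), n = length(idx)))
}

## Trailing/leading moving average with an odd window; edges use the
## shrunken symmetric window so no sample is dropped.
.movingAverage <- function(x, k) {
    if (k == 1) return(x)
    half <- (k - 1) / 2
    n <- length(x)
    vapply(seq_len(n), function(i) {
        lo <- max(1, i - half); hi <- min(n, i + half)
        mean(x[lo:hi])
    }, numeric(1))
}

#' Peak intensity and time to peak
#'
#' The trace is smoothed with a centered moving average of odd width
#' \code{smoothWindow}, the peak is the maximum of the smoothed trace, and
#' the time to peak is the first time it is attained (ties break earliest).
#'
#' @param trace a \code{\link{FluorescenceTrace-class}} object.
#' @param smoothWindow odd moving-average width in samples (default 5).
#' @return list with \code{peakIntensity} and \code{timeToPeak}.
#' @export
peakMetrics <- function(trace, smoothWindow = 5) {
    if (length(trace@time) == 0) stop("empty trace")
    if (smoothWindow %% 2 != 1 || smoothWindow < 1)
        stop("smoothWindow must be a positive odd integer")
    sm <- .movingAverage(trace@intensity, smoothWindow)
    i <- which.max(sm)
    list(peakIntensity = sm[i], timeToPeak = trace@time[i])
}

#' Half-maximal (log-phase) polymerization rate
#'
#' Least-squares slope around the half-maximal intensity.  In automatic
#' mode the baseline is the mean of the first three samples, the half-max
#' level is \code{baseline + 0.5 * (peak - baseline)} with the peak from
#' \code{\link{peakMetrics}}, and the fit window is the first crossing time
#' plus/minus \code{halfWidth} seconds (intersected with the trace).
#'
#' @param trace a \code{\link{FluorescenceTrace-class}} object.
#' @param window explicit fit window \code{c(start, end)} in seconds, or
#'   \code{NULL} (default) for automatic placement.
#' @param halfWidth half window width (s) in automatic mode.
#' @param smoothWindow passed to \code{\link{peakMetrics}}.
#' @return list with \code{slope}, \code{se}, \code{window}, \code{n} and,
#'   in automatic mode, \code{tHalf}.
#' @export
halfmaxRate <- function(trace, window = NULL, halfWidth = 30,
                        smoothWindow = 5) {
    tHalf <- NA_real_
    if (is.null(window)) {
        if (length(trace@time) < 3) stop("trace too short for auto window")
        baseline <- mean(trace@intensity[1:3])
        peak <- peakMetrics(trace, smoothWindow)$peakIntensity
        if (peak <= baseline + .Machine$double.eps^0.5 * (1 + abs(baseline)))
            stop("half-maximal level never reached: trace does not rise above baseline")
        level <- baseline + 0.5 * (peak - baseline)
        cross <- which(trace@intensity >= level)
        if (length(cross) == 0)
            stop("half-maximal level never reached")
        tHalf <- trace@time[cross[1]]
        window <- c(max(tHalf - halfWidth, min(trace@time)),
                    min(tHalf + halfWidth, max(trace@time)))
    }
    idx <- .windowIdx(trace, window)
    fit <- .fitSlope(trace@time[idx], trace@intensity[idx])
    c(fit, list(window = as.numeric(window), n = length(idx), tHalf = tHalf))
}

#' Quantify a trace into its four summary metrics
#'
#' @param trace a \code{\link{FluorescenceTrace-class}} object.
#' @param initialWindow window (s) for the initial rate.
#' @param halfWidth automatic half-max window half width (s).
#' @param smoothWindow odd smoothing width for the peak search.
#' @return a \code{\link{TraceMetrics-class}} object.
#' @export
quantifyTrace <- function(trace, initialWindow = c(0, 40), halfWidth = 30,
                          smoothWindow = 5) {
    ini <- initialRate(trace, initialWindow)
    hm <- halfmaxRate(trace, halfWidth = halfWidth,
                      smoothWindow = smoothWindow)
    pk <- peakMetrics(trace, smoothWindow)
    new("TraceMetrics", initialRate = ini$slope, initialRateSe = ini$se,
        halfmaxRate = hm$slope, halfmaxRateSe = hm$se,
        peakIntensity = pk$peakIntensity, timeToPeak = pk$timeToPeak,
        windows = list(initial = ini$window, halfmax = hm$window))
}

#' Fold change of a metric between two traces
#'
#' @param test,control \code{\link{TraceMetrics-class}} objects.
#' @param metric one of \code{"initialRate"}, \code{"halfmaxRate"},
#'   \code{"peakIntensity"}, \code{"timeToPeak"}.
#' @return test metric divided by control metric.
#' @export
foldChange <- function(test, control,
                       metric = c("initialRate", "halfmaxRate",
                                  "peakIntensity", "timeToPeak")) {
    metric <- match.arg(metric)
    stopifnot(is(test, "TraceMetrics"), is(control, "TraceMetrics"))
    denom <- slot(control, metric)
    if (denom == 0) stop("control ", metric, " is zero; fold change undefined")
    slot(test, metric) / denom
}

#' Polymerization-rate response to a mid-run nucleator addition
#'
#' Fits independent least-squares slopes immediately before
#' (\code{[tAdd - preWidth, tAdd)}) and after (\code{(tAdd, tAdd +
#' postWidth]}) the addition time and reports their ratio.
#'
#' @param trace a \code{\link{FluorescenceTrace-class}} object.
#' @param tAdd addition time (s).
#' @param preWidth,postWidth window widths (s).
#' @return list with \code{preSlope}, \code{postSlope} and \code{ratio}.
#' @export
additionResponse <- function(trace, tAdd, preWidth = 100, postWidth = 100) {
    t <- trace@time
    if (tAdd - preWidth < min(t) || tAdd + postWidth > max(t))
        stop("addition windows fall outside the trace")
    pre <- which(t >= tAdd - preWidth & t < tAdd)
    post <- which(t > tAdd & t <= tAdd + postWidth)
    if (length(pre) < 3 || length(post) < 3)
        stop("need at least 3 samples on each side of the addition")
    preFit <- .fitSlope(t[pre], trace@intensity[pre])
    postFit <- .fitSlope(t[post], trace@intensity[post])
    if (preFit$slope == 0) stop("pre-addition slope is zero; ratio undefined")
    list(preSlope = preFit$slope, postSlope = postFit$slope,
         ratio = postFit$slope / preFit$slope)
}
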