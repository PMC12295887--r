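## Points entering the Cc fit: intensity strictly above
## baseline + 3 * noiseSd.  The selection baseline defaults to the
## intensity of the lowest-concentration point (assumed at or below Cc)
## unless a blank level is supplied.
.ccPoints <- function(series, baseline, noiseSd) {
    if (is.null(baseline)) baseline <- series@intensity[1]
    keep <- series@intensity > baseline + 3 * noiseSd
    if (sum(keep) < 3)
        stop("fewer than 3 points above baseline + 3*noiseSd; ",
             "no rising limb to fit")
    list(conc = series@actinConc[keep], int = series@intensity[keep])
}

## Cc is where the fitted line crosses the blank level, floored at zero.
.ccFromLine <- function(slope, intercept, blank) {
    max(0, (blank - intercept) / slope)
}

#' Estimate the critical concentration from a steady-state series
#'
#' Classical steady-state pyrene construction: above the critical
#' concentration the steady-state intensity is affine in total actin, so a
#' least-squares line is fitted through the points whose intensity exceeds
#' \code{baseline + 3 * noiseSd}, and the critical concentration is where
#' that line falls back to the blank (baseline) level -- the x-intercept of
#' the blank-subtracted line, floored at 0.  Uncertainty comes from a
#' residual bootstrap: residuals of the fit are resampled with replacement
#' onto the fitted values and the line is refitted \code{bootstrapN} times.
#'
#' @param series a \code{\link{SteadyStateSeries-class}} object.
#' @param bootstrapN number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param baseline blank (no-polymer) intensity level.  When \code{NULL}
#'   (default) intensities are assumed blank-subtracted: the line is
#'   intersected with zero, while the lowest-concentration point still
#'   serves as the de facto baseline for point selection.
#' @param noiseSd known measurement noise sd used by the point-selection
#'   rule; default 0 keeps every point strictly above baseline.
#' @param level confidence level of the percentile interval.
#' @return a \code{\link{CcFit-class}} object.
#' @export
fitCc <- function(series, bootstrapN = 1000, seed = NA, baseline = NULL,
                  noiseSd = 0, level = 0.95) {
    stopifnot(is(series, "SteadyStateSeries"))
    validObject(series)
    pts <- .ccPoints(series, baseline, noiseSd)
    fit <- stats::lm(pts$int ~ pts$conc)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    if (!is.finite(slope) || slope <= 0)
        stop("fitted slope is not positive: intensity must increase with actin")
    blank <- if (is.null(baseline)) 0 else baseline
    cc <- .ccFromLine(slope, intercept, blank)

    res <- stats::residuals(fit)
    fitted <- stats::fitted(fit)
    if (!is.na(seed)) set.seed(seed)
    boot <- vapply(seq_len(bootstrapN), function(b) {
        yb <- fitted + sample(res, length(res), replace = TRUE)
        cb <- stats::coef(stats::lm(yb ~ pts$conc))
        if (!is.finite(cb[2]) || cb[2] <= 0) return(NA_real_)
        .ccFromLine(cb[2], cb[1], blank)
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    a <- (1 - level) / 2
    ci <- if (length(boot) > 0)
        unname(stats::quantile(boot, c(a, 1 - a))) else c(cc, cc)
    ci <- c(min(ci[1], cc), max(ci[2], cc))

    new("CcFit", slope = slope, intercept = intercept, cc = cc, ccCi = ci,
        nPointsUsed = length(pts$conc), bootstrapCc = boot,
        condition = series@condition)
}

#' Compare critical concentrations of two conditions
#'
#' Fits both series, forms \code{delta = ccA - ccB}, and derives a paired
#' bootstrap confidence interval by re-estimating both critical
#' concentrations from independently resampled residuals in each replicate.
#' The conditions are declared to share a critical concentration when the
#' interval contains zero.
#'
#' @param a,b \code{\link{SteadyStateSeries-class}} objects.
#' @param bootstrapN bootstrap replicates.
#' @param seed RNG seed.
#' @param ... passed on to \code{\link{fitCc}} (e.g. \code{noiseSd}).
#' @return list with \code{deltaCc}, \code{deltaCi}, \code{sameCc},
#'   \code{fitA}, \code{fitB}.
#' @export
compareCc <- function(a, b, bootstrapN = 1000, seed = NA, ...) {
    fitA <- fitCc(a, bootstrapN = bootstrapN, seed = seed, ...)
    fitB <- fitCc(b, bootstrapN = bootstrapN,
                  seed = if (is.na(seed)) NA else seed + 1, ...)
    n <- min(length(fitA@bootstrapCc), length(fitB@bootstrapCc))
    delta <- fitA@cc - fitB@cc
    if (n > 0) {
        deltas <- fitA@bootstrapCc[seq_len(n)] - fitB@bootstrapCc[seq_len(n)]
        ci <- unname(stats::quantile(deltas, c(0.025, 0.975)))
    } else ci <- c(delta, delta)
    ci <- c(min(ci[1], delta), max(ci[2], delta))
    list(deltaCc = delta, deltaCi = ci,
         sameCc = ci[1] <= 0 && ci[2] >= 0, fitA = fitA, fitB = fitB)
}
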