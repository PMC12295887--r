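#' Specify a paracrystal height image
#'
#' Parallel Gaussian ridges at a fixed inter-filament spacing spanning the
#' whole field, emulating the nematic paracrystals formed by long
#' (> 2 um) actin filaments on a supported lipid bilayer.  The default
#' 2 nm/px at 512 px gives a ~1 um field with the 13.3 nm spacing well
#' above Nyquist.
#'
#' @param sizePx image side (pixels).
#' @param pixelSize nm per pixel.
#' @param spacing inter-filament spacing (nm).
#' @param orientation filament axis angle from the image x axis (degrees);
#'   at 0 the filaments run along x and the lattice modulation runs along
#'   the row (y) index.
#' @param filamentSigma Gaussian ridge sigma (nm).
#' @param filamentHeight ridge height (nm).
#' @param noiseSd Gaussian pixel noise sd (nm).
#' @param seed RNG seed for the noise.
#' @return an \code{\link{ImageSpec-class}} object.
#' @export
paracrystalSpec <- function(sizePx = 512, pixelSize = 2, spacing = 13.3,
                            orientation = 0, filamentSigma = 4,
                            filamentHeight = 6, noiseSd = 0.3,
                            seed = NA_real_) {
    new("ImageSpec", sizePx = as.numeric(sizePx),
        pixelSize = as.numeric(pixelSize), mode = "paracrystal",
        spacing = as.numeric(spacing),
        filamentSigma = as.numeric(filamentSigma),
        filamentHeight = as.numeric(filamentHeight),
        orientation = as.numeric(orientation),
        nAsters = NA_real_, filamentsPerAster = NA_real_,
        filamentLength = NA_real_, globuleRadius = NA_real_,
        globuleHeight = NA_real_, minSeparation = NA_real_,
        noiseSd = as.numeric(noiseSd), seed = as.numeric(seed))
}

#' Specify a radial-aster height image
#'
#' Short filaments (below 1 um) radiating from focal globules, emulating
#' the radially symmetric actin complexes nucleated by PEVK seeds.
#'
#' @inheritParams paracrystalSpec
#' @param nAsters number of aster centers.
#' @param filamentsPerAster ridges per aster.
#' @param filamentLength maximum filament length (nm); individual lengths
#'   are drawn uniformly between 30% and 100% of this, capped below 1 um.
#' @param globuleRadius,globuleHeight focal globule Gaussian sigma and
#'   height (nm).
#' @param minSeparation minimum center-to-center distance (nm); rejection
#'   sampling errors out after bounded retries if it cannot be met.
#' @return an \code{\link{ImageSpec-class}} object.
#' @export
radialSpec <- function(sizePx = 512, pixelSize = 2, nAsters = 6,
                       filamentsPerAster = 8, filamentLength = 800,
                       globuleRadius = 20, globuleHeight = 10,
                       filamentSigma = 4, filamentHeight = 6,
                       minSeparation = 150, noiseSd = 0.3,
                       seed = NA_real_) {
    new("ImageSpec", sizePx = as.numeric(sizePx),
        pixelSize = as.numeric(pixelSize), mode = "radial",
        spacing = NA_real_, filamentSigma = as.numeric(filamentSigma),
        filamentHeight = as.numeric(filamentHeight),
        orientation = NA_real_, nAsters = as.numeric(nAsters),
        filamentsPerAster = as.numeric(filamentsPerAster),
        filamentLength = as.numeric(filamentLength),
        globuleRadius = as.numeric(globuleRadius),
        globuleHeight = as.numeric(globuleHeight),
        minSeparation = as.numeric(minSeparation),
        noiseSd = as.numeric(noiseSd), seed = as.numeric(seed))
}

## Pixel-center coordinate grids in nm.  Rows index y, columns x.
.coordGrids <- function(n, px) {
    ax <- (seq_len(n) - 1) * px
    list(X = matrix(ax, n, n, byrow = TRUE), Y = matrix(ax, n, n))
}

.addNoise <- function(h, spec) {
    if (spec@noiseSd > 0) {
        if (!is.na(spec@seed)) set.seed(spec@seed)
        h <- h + matrix(stats::rnorm(length(h), sd = spec@noiseSd),
                        nrow(h), ncol(h))
    }
    h
}

#' Render a paracrystal height image
#'
#' Heights are a periodic comb of Gaussian ridges,
#' \code{h(u) = height * sum_k exp(-(u - k*spacing)^2 / (2 sigma^2))},
#' where \code{u} is the coordinate perpendicular to the filament axis,
#' plus Gaussian pixel noise.  Deterministic under the seed carried in \code{spec}.
#'
#' @param spec an \code{\link{ImageSpec-class}} with mode
#'   \code{"paracrystal"}.
#' @return a \code{\link{HeightImage-class}} object.
#' @examples
#' img <- renderParacrystal(paracrystalSpec(sizePx = 128, noiseSd = 0))
#' @export
renderParacrystal <- function(spec) {
    stopifnot(is(spec, "ImageSpec"))
    validObject(spec)
    if (spec@mode != "paracrystal") stop("spec mode must be 'paracrystal'")
    n <- spec@sizePx
    g <- .coordGrids(n, spec@pixelSize)
    th <- spec@orientation * pi / 180
    u <- g$Y * cos(th) - g$X * sin(th)
    d <- spec@spacing
    v <- ((u %% d) + d) %% d
    reach <- ceiling(4 * spec@filamentSigma / d) + 1L
    h <- matrix(0, n, n)
    for (j in seq(-reach, reach))
        h <- h + exp(-(v - j * d)^2 / (2 * spec@filamentSigma^2))
    h <- spec@filamentHeight * h
    new("HeightImage", heights = .addNoise(h, spec),
        pixelSize = spec@pixelSize)
}

## Max-combine a Gaussian ridge along the segment (x1,y1)-(x2,y2) into h.
.paintSegment <- function(h, g, x1, y1, x2, y2, sigma, height, px) {
    pad <- 4 * sigma
    n <- nrow(h)
    cLo <- max(1L, floor((min(x1, x2) - pad) / px) + 1L)
    cHi <- min(n, ceiling((max(x1, x2) + pad) / px) + 1L)
    rLo <- max(1L, floor((min(y1, y2) - pad) / px) + 1L)
    rHi <- min(n, ceiling((max(y1, y2) + pad) / px) + 1L)
    if (cLo > cHi || rLo > rHi) return(h)
    cidx <- cLo:cHi
    ridx <- rLo:rHi
    X <- g$X[ridx, cidx, drop = FALSE]
    Y <- g$Y[ridx, cidx, drop = FALSE]
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx * vx + vy * vy
    tt <- if (L2 == 0) 0 else pmin(pmax(((X - x1) * vx + (Y - y1) * vy) / L2, 0), 1)
    d2 <- (X - x1 - tt * vx)^2 + (Y - y1 - tt * vy)^2
    h[ridx, cidx] <- pmax(h[ridx, cidx], height * exp(-d2 / (2 * sigma^2)))
    h
}

#' Render a radial-aster height image
#'
#' Aster centers are placed by rejection sampling at pairwise distance of
#' at least \code{minSeparation} (erroring after bounded retries).  Each
#' aster gets a central Gaussian globule and \code{filamentsPerAster}
#' Gaussian ridges at uniformly random angles with lengths drawn below the
#' maximum filament length.  Overlapping features combine by maximum, and
#' Gaussian pixel noise is added last.  Deterministic under the seed carried in \code{spec}.
#'
#' @param spec an \code{\link{ImageSpec-class}} with mode \code{"radial"}.
#' @return a \code{\link{HeightImage-class}} object.
#' @export
renderRadial <- function(spec) {
    stopifnot(is(spec, "ImageSpec"))
    validObject(spec)
    if (spec@mode != "radial") stop("spec mode must be 'radial'")
    n <- spec@sizePx
    px <- spec@pixelSize
    field <- n * px
    g <- .coordGrids(n, px)
    h <- matrix(0, n, n)
    if (!is.na(spec@seed)) set.seed(spec@seed)

    nA <- spec@nAsters
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < nA) {
        cand <- stats::runif(2, 0.05 * field, 0.95 * field)
        ok <- nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cand[1])^2 +
                     (centers[, 2] - cand[2])^2) >= spec@minSeparation)
        if (ok) centers <- rbind(centers, cand)
        tries <- tries + 1
        if (tries > 500 * max(nA, 1))
            stop("could not place ", nA, " aster centers at minimum ",
                 "separation ", spec@minSeparation, " nm")
    }

    maxLen <- min(spec@filamentLength, 1000)
    for (a in seq_len(nA)) {
        cx <- centers[a, 1]; cy <- centers[a, 2]
        # focal globule
        h <- .paintSegment(h, g, cx, cy, cx, cy, spec@globuleRadius,
                           spec@globuleHeight, px)
        for (f in seq_len(spec@filamentsPerAster)) {
            ang <- stats::runif(1, 0, 2 * pi)
            len <- stats::runif(1, 0.3, 1) * maxLen
            h <- .paintSegment(h, g, cx, cy,
                               cx + len * cos(ang), cy + len * sin(ang),
                               spec@filamentSigma, spec@filamentHeight, px)
        }
    }
    if (spec@noiseSd > 0)
        h <- h + matrix(stats::rnorm(length(h), sd = spec@noiseSd), n, n)
    new("HeightImage", heights = h, pixelSize = px)
}

.fftshift2 <- function(m) {
    n <- nrow(m)
    half <- n %/% 2
    idx <- c((half + 1):n, 1:half)
    m[idx, idx]
}

#' 2D amplitude spectrum of a height image
#'
#' Amplitude of the discrete 2D Fourier transform of the mean-subtracted,
#' Hann-windowed image, zero frequency centered.  Frequency axes are in
#' per-meter units derived from the pixel size.  Amplitudes are raw DFT
#' magnitudes; only peak positions, not absolute amplitudes, are intended
#' to be compared across images.
#'
#' @param image a square \code{\link{HeightImage-class}} object.
#' @return an \code{\link{AmplitudeSpectrum-class}} object.
#' @export
fftAmplitude <- function(image) {
    stopifnot(is(image, "HeightImage"))
    h <- image@heights
    n <- nrow(h)
    if (n != ncol(h)) stop("image must be square")
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
    hw <- (h - mean(h)) * (w %o% w)
    amp <- .fftshift2(Mod(stats::fft(hw)))
    freq <- (seq_len(n) - 1 - n %/% 2) / (n * image@pixelSize) * 1e9
    new("AmplitudeSpectrum", amplitude = amp, frequency = freq,
        pixelSize = image@pixelSize)
}

## Radial frequency bin width (per m) of a spectrum.
.binWidth <- function(spectrum) {
    1 / (length(spectrum@frequency) * spectrum@pixelSize) * 1e9
}

#' Directional amplitude spectrum
#'
#' Averages the 2D spectrum over the angular sector \code{angle +/-
#' halfWidth} (and its point reflection, since the amplitude spectrum of a
#' real image is centro-symmetric), binned by radial spatial frequency in
#' bins of one DFT frequency step.  Empty bins are reported as \code{NA},
#' not zero.
#'
#' @param spectrum an \code{\link{AmplitudeSpectrum-class}} object.
#' @param angle probe direction in degrees within [0, 180); 90 degrees
#'   probes along the image y (row) axis.
#' @param halfWidth angular half width of the sector (degrees).
#' @return data.frame with columns \code{spatialFrequency} (per m),
#'   \code{periodicity} (nm), \code{amplitude} and \code{nPixels} (Fourier
#'   pixels contributing to the bin), plus attributes \code{angle} and
#'   \code{binWidth}.
#' @export
directionalSpectrum <- function(spectrum, angle, halfWidth = 10) {
    stopifnot(is(spectrum, "AmplitudeSpectrum"))
    if (angle < 0 || angle >= 180) stop("angle must lie in [0, 180)")
    fr <- spectrum@frequency
    FX <- matrix(fr, length(fr), length(fr), byrow = TRUE)
    FY <- matrix(fr, length(fr), length(fr))
    r <- sqrt(FX^2 + FY^2)
    a <- (atan2(FY, FX) * 180 / pi) %% 180
    dAng <- abs(a - angle)
    dAng <- pmin(dAng, 180 - dAng)
    df <- .binWidth(spectrum)
    sel <- dAng <= halfWidth & r > df / 2
    bins <- as.integer(round(r[sel] / df))
    amps <- spectrum@amplitude[sel]
    nBins <- length(fr) %/% 2
    out <- rep(NA_real_, nBins)
    cnt <- rep(0L, nBins)
    agg <- tapply(amps, bins, mean)
    nagg <- tapply(amps, bins, length)
    idx <- as.integer(names(agg))
    ok <- idx >= 1 & idx <= nBins
    out[idx[ok]] <- agg[ok]
    cnt[idx[ok]] <- as.integer(nagg[ok])
    res <- data.frame(spatialFrequency = seq_len(nBins) * df,
                      periodicity = 1e9 / (seq_len(nBins) * df),
                      amplitude = out, nPixels = cnt)
    attr(res, "angle") <- angle
    attr(res, "binWidth") <- df
    res
}

## Topographic prominence of a local maximum at index i of x.
.prominence <- function(x, i) {
    h <- x[i]
    lo <- h
    j <- i
    while (j > 1) {
        j <- j - 1
        if (x[j] > h) break
        lo <- min(lo, x[j])
    }
    leftMin <- lo
    lo <- h
    j <- i
    while (j < length(x)) {
        j <- j + 1
        if (x[j] > h) break
        lo <- min(lo, x[j])
    }
    h - max(leftMin, lo)
}

#' Detect spatial periodicities in a directional spectrum
#'
#' Local maxima of the in-band profile whose topographic prominence
#' exceeds \code{prominenceFactor} times the median absolute deviation of
#' the in-band amplitudes, and which also rise that far above the in-band
#' median amplitude (a distinct peak must stand above the continuum, not
#' merely above its own neighbouring dips).  Because a bin's amplitude is the mean over the
#' Fourier pixels falling in its sector-annulus cell, sparsely populated
#' low-frequency bins fluctuate far more than the band-wide MAD suggests;
#' each bin's threshold is therefore scaled by the standard-error factor
#' \code{sqrt(Kmed / K)} of its pixel count \code{K} relative to the
#' median in-band count.  Band membership is tested with half a
#' frequency bin of slack at each edge, the natural resolution of a
#' discrete spectrum (the printed band limits are rounded values).
#'
#' @param profile a directional spectrum as returned by
#'   \code{\link{directionalSpectrum}}.
#' @param band spatial-frequency band (per m); the default 5e6-75e6 per m
#'   corresponds to periodicities of 200 nm down to ~13.3 nm.
#' @param prominenceFactor prominence threshold in MAD units (default 5).
#' @return a \code{\link{PeriodicityResult-class}} object; peaks are
#'   sorted by amplitude, ties broken towards lower frequency.
#' @export
detectPeriodicities <- function(profile, band = c(5e6, 75e6),
                                prominenceFactor = 5) {
    if (length(band) != 2 || band[1] >= band[2] || band[1] <= 0)
        stop("band must be (low, high) per m with 0 < low < high")
    df <- attr(profile, "binWidth")
    if (is.null(df)) df <- min(diff(profile$spatialFrequency))
    nyq <- max(profile$spatialFrequency)
    if (band[1] > nyq)
        stop("band lies outside the Nyquist range of this profile")
    full <- profile[!is.na(profile$amplitude), , drop = FALSE]
    inBand <- full$spatialFrequency >= band[1] - df / 2 &
              full$spatialFrequency <= band[2] + df / 2
    if (sum(inBand) < 3)
        stop("profile does not cover the requested band")
    ## local maxima and prominences are judged on the full profile so that
    ## a genuine maximum sitting at a band edge is not lost to truncation
    x <- full$amplitude
    madBand <- stats::mad(x[inBand])
    medBand <- stats::median(x[inBand])
    k <- if ("nPixels" %in% names(full)) full$nPixels else
        rep(1L, length(x))
    kMed <- stats::median(k[inBand & k > 0])
    hits <- integer(0)
    proms <- numeric(0)
    for (i in seq_along(x)[inBand]) {
        left <- if (i == 1) -Inf else x[i - 1]
        right <- if (i == length(x)) -Inf else x[i + 1]
        if (x[i] > left && x[i] >= right) {
            p <- .prominence(x, i)
            thr <- prominenceFactor * madBand *
                max(1, sqrt(kMed / max(k[i], 1)))
            # a distinct peak must rise above the in-band continuum, not
            # merely above its own neighbouring dips
            if (p > thr && x[i] > medBand + thr) {
                hits <- c(hits, i)
                proms <- c(proms, p)
            }
        }
    }
    pk <- data.frame(spatialFrequency = full$spatialFrequency[hits],
                     periodicity = full$periodicity[hits],
                     amplitude = x[hits], prominence = proms)
    pk <- pk[order(-pk$amplitude, pk$spatialFrequency), , drop = FALSE]
    rownames(pk) <- NULL
    ang <- attr(profile, "angle")
    new("PeriodicityResult", peaks = pk, band = as.numeric(band),
        hasPeriodicity = nrow(pk) > 0,
        angle = if (is.null(ang)) NA_real_ else ang)
}

#' Detect lattice order in a height image
#'
#' Blind pipeline used for paracrystal-versus-aster classification:
#' computes the 2D amplitude spectrum, locates the strongest in-band
#' spectral pixel to choose the probe direction, extracts the directional
#' spectrum along it, and runs \code{\link{detectPeriodicities}}.  No
#' knowledge of the true filament orientation is used.
#'
#' @param image a \code{\link{HeightImage-class}} object.
#' @param band spatial-frequency band (per m).
#' @param halfWidth angular sector half width (degrees).
#' @param prominenceFactor prominence threshold in MAD units.
#' @return a \code{\link{PeriodicityResult-class}} object whose
#'   \code{angle} slot records the probed direction.
#' @export
detectLatticeSpacing <- function(image, band = c(5e6, 75e6), halfWidth = 10,
                                 prominenceFactor = 5) {
    sp <- fftAmplitude(image)
    fr <- sp@frequency
    FX <- matrix(fr, length(fr), length(fr), byrow = TRUE)
    FY <- matrix(fr, length(fr), length(fr))
    r <- sqrt(FX^2 + FY^2)
    df <- .binWidth(sp)
    mask <- r >= band[1] - df / 2 & r <= band[2] + df / 2
    amp <- sp@amplitude
    amp[!mask] <- -Inf
    i <- arrayInd(which.max(amp), dim(amp))
    ang <- (atan2(FY[i], FX[i]) * 180 / pi) %% 180
    if (ang >= 180) ang <- 0
    prof <- directionalSpectrum(sp, ang, halfWidth)
    detectPeriodicities(prof, band, prominenceFactor)
}
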