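test_that("a zero-orientation paracrystal varies only along the row index", {
    spec <- paracrystalSpec(sizePx = 128, pixelSize = 2, spacing = 13.3,
                            orientation = 0, noiseSd = 0)
    img <- renderParacrystal(spec)
    h <- heights(img)
    # all columns identical
    expect_lt(max(abs(h - h[, 1])), 1e-12)
    # profile along rows periodic with period spacing/pixelSize
    prof <- h[, 1]
    shift <- 13.3 / 2 * 10   # 10 full periods = 66.5 px, not integer; use
    # autocorrelation instead: the lag nearest one period has max correlation
    ac <- stats::acf(prof - mean(prof), lag.max = 20, plot = FALSE)$acf[-1]
    expect_equal(which.max(ac), round(13.3 / 2))
})

test_that("well-separated ridges peak at the configured height", {
    spec <- paracrystalSpec(sizePx = 128, spacing = 40, filamentSigma = 3,
                            filamentHeight = 6, noiseSd = 0)
    img <- renderParacrystal(spec)
    expect_equal(max(heights(img)), 6, tolerance = 1e-3)
})

test_that("rendering is deterministic under a seed and noise-only otherwise", {
    s1 <- paracrystalSpec(sizePx = 128, noiseSd = 0.3, seed = 5)
    expect_identical(heights(renderParacrystal(s1)),
                     heights(renderParacrystal(s1)))
    s2 <- paracrystalSpec(sizePx = 128, noiseSd = 0.3, seed = 6)
    d <- heights(renderParacrystal(s1)) - heights(renderParacrystal(s2))
    # the deterministic ridge component cancels; what remains is the
    # difference of two noise fields (sd 0.3 * sqrt(2))
    expect_lt(max(abs(d)), 8 * 0.3)
    expect_gt(stats::sd(d), 0.3)

    r1 <- radialSpec(sizePx = 128, nAsters = 2, minSeparation = 60,
                     filamentLength = 150, seed = 11)
    expect_identical(heights(renderRadial(r1)), heights(renderRadial(r1)))
})

test_that("image specs are validated", {
    expect_error(paracrystalSpec(sizePx = 32), ">= 64")
    expect_error(paracrystalSpec(spacing = 3, pixelSize = 2), "Nyquist")
    expect_error(renderRadial(paracrystalSpec()), "radial")
    expect_error(renderParacrystal(radialSpec()), "paracrystal")
    expect_error(renderRadial(radialSpec(sizePx = 128, nAsters = 40,
                                         minSeparation = 400)),
                 "could not place")
})

test_that("an empty radial field is flat noise; aster ridges pass through their center", {
    flat <- renderRadial(radialSpec(sizePx = 128, nAsters = 0, noiseSd = 0))
    expect_equal(max(abs(heights(flat))), 0)

    one <- renderRadial(radialSpec(sizePx = 256, nAsters = 1,
                                   filamentsPerAster = 8,
                                   filamentLength = 200, noiseSd = 0,
                                   seed = 3))
    h <- heights(one)
    ctr <- which(h == max(h), arr.ind = TRUE)[1, ]
    # the globule dominates at the center
    expect_equal(max(h), 10, tolerance = 0.01)
    # walk a small circle around the center: ridge crests there reach the
    # filament height, and there are several distinct crests
    px <- 2
    ang <- seq(0, 2 * pi, length.out = 721)[-721]
    r <- 60 / px
    vals <- h[cbind(pmin(pmax(round(ctr[1] + r * sin(ang)), 1), 256),
                    pmin(pmax(round(ctr[2] + r * cos(ang)), 1), 256))]
    expect_equal(max(vals), 6, tolerance = 0.05)
    crests <- sum(diff(vals > 3) == 1)
    expect_gte(crests, 4)
})

test_that("the 2D spectrum behaves like a Fourier transform", {
    # constant image: all-zero spectrum after mean subtraction
    img <- new("HeightImage", heights = matrix(3.7, 64, 64), pixelSize = 2)
    expect_equal(max(fftAmplitude(img)@amplitude), 0)

    # pure cosine of period 16 px concentrates near +/- 1/(16 px)
    n <- 128; px <- 2
    x <- matrix(rep(0:(n - 1), each = n), n, n, byrow = TRUE)
    img <- new("HeightImage",
               heights = cos(2 * pi * x / 16), pixelSize = px)
    sp <- fftAmplitude(img)
    i <- arrayInd(which.max(sp@amplitude), dim(sp@amplitude))
    fpk <- sqrt(sp@frequency[i[1]]^2 + sp@frequency[i[2]]^2)
    expect_equal(fpk, 1 / (16 * px) * 1e9, tolerance = 1e-6)

    # Parseval: spectral energy equals windowed-image energy
    set.seed(13)
    h <- matrix(rnorm(64^2), 64, 64)
    img <- new("HeightImage", heights = h, pixelSize = 2)
    sp <- fftAmplitude(img)
    w <- 0.5 * (1 - cos(2 * pi * (0:63) / 64))
    hw <- (h - mean(h)) * (w %o% w)
    expect_equal(sum(sp@amplitude^2) / 64^2, sum(hw^2), tolerance = 1e-6)

    expect_error(fftAmplitude(new("HeightImage",
                                  heights = matrix(0, 4, 4),
                                  pixelSize = 1)),
                 NA)
})

test_that("directional spectra see the lattice only perpendicular to the filaments", {
    img <- renderParacrystal(paracrystalSpec(noiseSd = 0))
    sp <- fftAmplitude(img)
    perp <- detectPeriodicities(directionalSpectrum(sp, 90))
    expect_true(hasPeriodicity(perp))
    expect_equal(peaks(perp)$periodicity[1], 13.3, tolerance = 0.01)
    para <- detectPeriodicities(directionalSpectrum(sp, 0))
    expect_false(hasPeriodicity(para))
})

test_that("the 13.3 nm fundamental is in band and its 6.65 nm harmonic is excluded", {
    img <- renderParacrystal(paracrystalSpec(noiseSd = 0))
    prof <- directionalSpectrum(fftAmplitude(img), 90)
    res <- detectPeriodicities(prof)
    pk <- peaks(res)
    expect_true(all(pk$periodicity > 10))
    # yet the harmonic is present in the raw profile outside the band
    harm <- prof[abs(prof$spatialFrequency - 2 * 75.19e6) < 2e6, ]
    expect_gt(max(harm$amplitude, na.rm = TRUE),
              10 * stats::median(prof$amplitude, na.rm = TRUE))
})

test_that("angles, bands and sparse profiles are validated", {
    img <- renderParacrystal(paracrystalSpec(sizePx = 128, noiseSd = 0))
    sp <- fftAmplitude(img)
    expect_error(directionalSpectrum(sp, 180), "\\[0, 180\\)")
    prof <- directionalSpectrum(sp, 90)
    expect_error(detectPeriodicities(prof, band = c(75e6, 5e6)), "low < high")
    expect_error(detectPeriodicities(prof, band = c(1e9, 2e9)), "Nyquist")
    # empty sector bins are NA, never zero
    narrow <- directionalSpectrum(sp, 37, halfWidth = 2)
    expect_true(anyNA(narrow$amplitude))
    expect_false(any(narrow$amplitude == 0, na.rm = TRUE))
})

test_that("planted spacings are recovered within one radial frequency bin", {
    binHz <- 1 / (512 * 2) * 1e9
    for (d in c(8, 13.3, 25, 40)) {
        for (seed in 1:3) {
            spec <- paracrystalSpec(spacing = d, noiseSd = 0.3, seed = seed,
                                    orientation = 17)
            res <- detectLatticeSpacing(renderParacrystal(spec),
                                        band = c(5e6, 2e8))
            expect_true(hasPeriodicity(res))
            fTop <- peaks(res)$spatialFrequency[1]
            expect_lt(abs(fTop - 1e9 / d), binHz + 1e-6)
        }
    }
})

test_that("rotating the lattice rotates the spectral peak by the same angle", {
    angOf <- function(orient) {
        img <- renderParacrystal(paracrystalSpec(orientation = orient,
                                                 noiseSd = 0))
        sp <- fftAmplitude(img)
        fr <- sp@frequency
        FX <- matrix(fr, length(fr), length(fr), byrow = TRUE)
        FY <- matrix(fr, length(fr), length(fr))
        r <- sqrt(FX^2 + FY^2)
        a <- sp@amplitude
        a[r < 5e6 | r > 76e6] <- -Inf
        i <- arrayInd(which.max(a), dim(a))
        (atan2(FY[i], FX[i]) * 180 / pi) %% 180
    }
    a0 <- angOf(0)
    a30 <- angOf(30)
    a75 <- angOf(75)
    expect_equal((a30 - a0) %% 180, 30, tolerance = 1.5)
    expect_equal((a75 - a0) %% 180, 75, tolerance = 1.5)
})

test_that("flat-noise images rarely trigger the periodicity detector", {
    fp <- 0
    for (i in 1:100) {
        set.seed(7000 + i)
        h <- matrix(rnorm(256^2, sd = 0.3), 256, 256)
        img <- new("HeightImage", heights = h, pixelSize = 2)
        prof <- directionalSpectrum(fftAmplitude(img), 90)
        if (hasPeriodicity(detectPeriodicities(prof))) fp <- fp + 1
    }
    expect_lt(fp / 100, 0.05)
})

test_that("radial aster fields show no lattice periodicity", {
    hits <- 0
    for (i in 1:12) {
        img <- renderRadial(radialSpec(seed = 500 + i))
        if (hasPeriodicity(detectLatticeSpacing(img))) hits <- hits + 1
    }
    expect_lte(hits, 1)
})
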