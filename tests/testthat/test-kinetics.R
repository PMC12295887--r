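test_that("degenerate inputs give empty kinetics", {
    t <- seq(0, 100, by = 1)

    # no material at all
    st <- simulatePolymerization(KineticParams(actinTotal = 0), t)
    expect_equal(max(polymer(st)), 0)
    expect_equal(max(filaments(st)), 0)

    # no nucleation pathway: monomer never converts
    p <- KineticParams(kNuc = 0, kSeed = 0, nucleatorConc = 0)
    st <- simulatePolymerization(p, t)
    expect_equal(monomer(st), rep(4, length(t)), tolerance = 1e-8)
    expect_equal(max(polymer(st)), 0, tolerance = 1e-8)
})

test_that("invalid parameters and grids are rejected", {
    expect_error(KineticParams(kPlus = -1), "non-negative")
    expect_error(KineticParams(nucleusSize = 1), "integer >= 2")
    expect_error(KineticParams(labeledFraction = 1.5), "\\[0, 1\\]")
    expect_error(simulatePolymerization(KineticParams(), c(1, 2, 3)),
                 "starting at 0")
    expect_error(simulatePolymerization(KineticParams(), c(0, 5, 5)),
                 "strictly increasing")
    expect_error(
        simulatePolymerization(KineticParams(), 0:10,
            events = data.frame(time = 5, deltaNucleator = -1)),
        "non-negative")
})

test_that("monomer converges to the critical concentration kMinus/kPlus", {
    p <- KineticParams()   # kPlus 11.6, kMinus 1.4, 4 uM >> Cc
    st <- simulatePolymerization(p, seq(0, 10000, by = 20))
    expect_equal(tail(monomer(st), 1), criticalConcentration(p),
                 tolerance = 1e-4)
    # spontaneous-only run converges to the same fixed point
    p2 <- KineticParams(kSeed = 0)
    st2 <- simulatePolymerization(p2, seq(0, 10000, by = 20))
    expect_equal(tail(monomer(st2), 1), 1.4 / 11.6, tolerance = 1e-3)
})

test_that("mass is conserved and filaments never decrease across parameter sets", {
    grid <- expand.grid(nuc = c(0, 32.5, 125), actin = c(0.5, 4),
                        kNuc = c(0, 7.5e-9))
    for (i in seq_len(nrow(grid))) {
        p <- KineticParams(kNuc = grid$kNuc[i], nucleatorConc = grid$nuc[i],
                           actinTotal = grid$actin[i])
        st <- simulatePolymerization(p, seq(0, 3000, by = 10))
        expect_lt(max(abs(monomer(st) + polymer(st) - grid$actin[i])), 1e-6)
        expect_true(all(diff(filaments(st)) > -1e-10))
        expect_true(all(monomer(st) >= -1e-8))
        expect_true(all(polymer(st) >= -1e-8))
    }
})

test_that("doubling the nucleator never slows pre-steady-state assembly", {
    t <- seq(0, 500, by = 5)
    for (conc in c(3.25, 16.25, 62.5)) {
        a <- simulatePolymerization(KineticParams(nucleatorConc = conc), t)
        b <- simulatePolymerization(KineticParams(nucleatorConc = 2 * conc), t)
        expect_true(all(polymer(b) - polymer(a) >= -1e-9))
    }
})

test_that("a nucleator addition at t = 0 equals nucleator present from the start", {
    ev <- data.frame(time = 0, deltaNucleator = 50)
    a <- simulatePolymerization(KineticParams(), shortGrid, events = ev)
    b <- simulatePolymerization(KineticParams(nucleatorConc = 50), shortGrid)
    expect_identical(polymer(a), polymer(b))
    expect_identical(filaments(a), filaments(b))
})

test_that("mid-run nucleator addition takes effect at the event time", {
    ev <- data.frame(time = 500, deltaNucleator = 125)
    withEv <- simulatePolymerization(KineticParams(), shortGrid, events = ev)
    without <- simulatePolymerization(KineticParams(), shortGrid)
    pre <- shortGrid <= 500
    expect_equal(polymer(withEv)[pre], polymer(without)[pre],
                 tolerance = 1e-7)
    expect_gt(polymer(withEv)[match(800, shortGrid)],
              polymer(without)[match(800, shortGrid)])
})

test_that("fluorescence observation is the affine bleach-free identity when switched off", {
    st <- simulatePolymerization(KineticParams(nucleatorConc = 32.5),
                                 seq(0, 800, by = 4))
    obs <- quietObs(gain = 500, baseline = 7)
    tr <- observeFluorescence(st, obs)
    expect_equal(intensity(tr) - 7, 500 * 0.1 * polymer(st),
                 tolerance = 1e-12)
})

test_that("constant polymer under continuous illumination bleaches exponentially", {
    p <- KineticParams(kNuc = 0, kSeed = 0)
    st <- new("KineticState", time = seq(0, 1000, by = 10),
              monomer = rep(2, 101), polymer = rep(2, 101),
              filaments = rep(0.001, 101),
              params = KineticParams(actinTotal = 4))
    obs <- ObservationParams(gain = 100, baseline = 0, kBleach = 2e-3,
                             noiseSd = 0)
    tr <- observeFluorescence(st, obs)
    expect_equal(intensity(tr), 100 * 0.1 * 2 * exp(-2e-3 * traceTime(tr)),
                 tolerance = 1e-12)
})

test_that("intermittent illumination accumulates less bleach than continuous", {
    st <- simulatePolymerization(KineticParams(nucleatorConc = 60),
                                 seq(0, 4000, by = 1))
    cont <- observeFluorescence(st, ObservationParams(kBleach = 5e-4,
                                                      noiseSd = 0))
    intm <- observeFluorescence(st, ObservationParams(kBleach = 5e-4,
        noiseSd = 0, schedule = IlluminationSchedule("intermittent")))
    shared <- match(traceTime(intm), traceTime(cont))
    expect_true(all(intensity(intm) >= intensity(cont)[shared] - 1e-9))
    # and intermittent traces only contain illuminated times
    expect_true(all(traceTime(intm) %% 600 <= 10 + 1e-9))
})

test_that("observation noise is reproducible under a seed", {
    st <- simulatePolymerization(KineticParams(), seq(0, 500, by = 5))
    obs <- ObservationParams(noiseSd = 3, seed = 42)
    expect_identical(intensity(observeFluorescence(st, obs)),
                     intensity(observeFluorescence(st, obs)))
    obs2 <- ObservationParams(noiseSd = 3, seed = 43)
    expect_false(identical(intensity(observeFluorescence(st, obs)),
                           intensity(observeFluorescence(st, obs2))))
})

test_that("a dose series is ordered, labeled, and deterministic", {
    t <- seq(0, 400, by = 2)
    obs <- ObservationParams(noiseSd = 1, seed = 7, kBleach = 0)
    trs <- simulateDoseSeries(KineticParams(), c(3.25, 6.5, 16.25, 32.5),
                              t, obs)
    expect_length(trs, 4)
    expect_equal(condition(trs[[2]]), "nucleator_6.5_nM")
    trs2 <- simulateDoseSeries(KineticParams(), c(3.25, 6.5, 16.25, 32.5),
                               t, obs)
    expect_identical(lapply(trs, intensity), lapply(trs2, intensity))

    # noise off: early slope non-decreasing in nucleator concentration
    quiet <- simulateDoseSeries(KineticParams(), c(3.25, 6.5, 16.25, 32.5),
                                t, quietObs())
    slopes <- vapply(quiet, function(x) initialRate(x)$slope, numeric(1))
    expect_false(is.unsorted(slopes))

    # zero-concentration series reduces to the control
    z <- simulateDoseSeries(KineticParams(), 0, t, quietObs())
    ctrl <- observeFluorescence(simulatePolymerization(KineticParams(), t),
                                quietObs())
    expect_equal(intensity(z[[1]]), intensity(ctrl))
    expect_error(simulateDoseSeries(KineticParams(), numeric(0), t, obs),
                 "non-empty")
})

test_that("steady-state series has the analytic affine form above Cc", {
    base <- KineticParams(nucleatorConc = 60)
    concs <- c(0.4, 0.8, 1.2, 1.6, 2.0)   # all well above Cc = 0.1207
    obs <- quietObs(gain = 1000, baseline = 20,
                    schedule = IlluminationSchedule("intermittent"))
    s <- simulateCcSeries(base, concs, tEnd = 8000, obs = obs)
    cc <- criticalConcentration(base)
    expect_equal(intensity(s), 20 + 1000 * 0.1 * (concs - cc),
                 tolerance = 1e-3)
})

test_that("below the critical concentration the steady-state signal stays at baseline", {
    base <- KineticParams(nucleatorConc = 60)
    s <- simulateCcSeries(base, c(0.02, 0.06, 0.1), tEnd = 8000,
                          obs = quietObs(baseline = 20,
                              schedule = IlluminationSchedule("intermittent")))
    expect_equal(intensity(s), rep(20, 3), tolerance = 0.05)
})

test_that("cc series validates input and flags unreached steady state", {
    base <- KineticParams(nucleatorConc = 60)
    expect_error(simulateCcSeries(base, c(-0.1, 1)), ">= 0")
    expect_error(simulateCcSeries(base, numeric(0)), "non-empty")
    expect_error(simulateCcSeries(KineticParams(nucleatorConc = 60),
                                  2, tEnd = 200),
                 "steady state not reached")
})
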