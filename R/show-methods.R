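.s3 <- function(x) signif(x, 3)

setMethod("show", "KineticParams", function(object) {
    cat("KineticParams:",
        sprintf("kPlus = %g /uM/s, kMinus = %g /s (Cc = %.3g uM)",
                object@kPlus, object@kMinus,
                if (object@kPlus > 0) object@kMinus / object@kPlus else NA),
        "\n  nucleation:",
        sprintf("kNuc = %g (n = %d), kSeed = %g (order %d), nucleator = %g nM",
                object@kNuc, as.integer(object@nucleusSize), object@kSeed,
                as.integer(object@seedOrder), object@nucleatorConc),
        "\n  actin:",
        sprintf("%g uM total, %g%% labeled\n", object@actinTotal,
                100 * object@labeledFraction))
})

setMethod("show", "KineticState", function(object) {
    n <- length(object@time)
    cat(sprintf(
        "KineticState: %d time points over %g s\n  final monomer %.4g uM, polymer %.4g uM, filaments %.4g uM\n",
        n, object@time[n], object@monomer[n], object@polymer[n],
        object@filaments[n]))
})

setMethod("show", "FluorescenceTrace", function(object) {
    cat(sprintf(
        "FluorescenceTrace '%s': %d samples, t = %g..%g s (%s illumination)\n",
        object@condition, length(object@time), min(object@time),
        max(object@time), object@schedule@mode))
})

setMethod("show", "TraceMetrics", function(object) {
    cat("TraceMetrics:\n",
        sprintf("  initial rate  %.4g +/- %.2g au/s\n", object@initialRate,
                object@initialRateSe),
        sprintf("  halfmax rate  %.4g +/- %.2g au/s\n", object@halfmaxRate,
                object@halfmaxRateSe),
        sprintf("  peak          %.4g au at t = %g s\n",
                object@peakIntensity, object@timeToPeak), sep = "")
})

setMethod("show", "SteadyStateSeries", function(object) {
    cat(sprintf(
        "SteadyStateSeries '%s': %d points, actin %g..%g uM\n",
        object@condition, length(object@actinConc), min(object@actinConc),
        max(object@actinConc)))
})

setMethod("show", "CcFit", function(object) {
    cat(sprintf(
        "CcFit '%s': Cc = %.4g uM (95%% CI %.4g..%.4g), slope %.4g au/uM, %d points\n",
        object@condition, object@cc, object@ccCi[1], object@ccCi[2],
        object@slope, as.integer(object@nPointsUsed)))
})

setMethod("show", "ChainGeometry", function(object) {
    cat(sprintf(
        "ChainGeometry: %d residues x %g nm\n  Lc = %g nm, Lp = %g nm, R = %g nm, RG = %g nm  (3 s.f.)\n",
        as.integer(object@nResidues), object@residueSpacing,
        .s3(object@contourLength), object@persistenceLength,
        .s3(object@endToEnd), .s3(object@radiusOfGyration)))
})

setMethod("show", "LatticeGeometry", function(object) {
    cat(sprintf(
        "LatticeGeometry: d10 = %g nm, thick-thin distance = %g nm\n  RG = %g nm, reach margin = %g nm\n",
        object@d10, .s3(object@thickThinDistance),
        .s3(object@radiusOfGyration), .s3(object@reachMargin)))
})

setMethod("show", "HeightImage", function(object) {
    cat(sprintf(
        "HeightImage: %d x %d px at %g nm/px (%g nm field), heights %.3g..%.3g nm\n",
        nrow(object@heights), ncol(object@heights), object@pixelSize,
        nrow(object@heights) * object@pixelSize, min(object@heights),
        max(object@heights)))
})

setMethod("show", "PeriodicityResult", function(object) {
    cat(sprintf(
        "PeriodicityResult: %s (band %.3g..%.3g /m%s)\n",
        if (object@hasPeriodicity) "periodicity detected" else "no periodicity",
        object@band[1], object@band[2],
        if (is.na(object@angle)) "" else sprintf(", probe %g deg",
                                                 object@angle)))
    if (nrow(object@peaks) > 0) {
        top <- utils::head(object@peaks, 3)
        for (i in seq_len(nrow(top)))
            cat(sprintf("  %.4g nm (SF %.4g /m, amplitude %.3g)\n",
                        top$periodicity[i], top$spatialFrequency[i],
                        top$amplitude[i]))
    }
})
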