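# Shared fixtures: small grids and quiet observation defaults keep the
# suite fast; individual tests override what they probe.

quietObs <- function(...) ObservationParams(noiseSd = 0, kBleach = 0, ...)

shortGrid <- seq(0, 2000, by = 5)

# Closed-form two-pass least-squares slope, the independent oracle for
# every lm-based slope in the package.
slopeOracle <- function(t, f) {
    sum((t - mean(t)) * (f - mean(f))) / sum((t - mean(t))^2)
}

# Synthetic straight-line trace.
lineTrace <- function(a, b, t = 0:40) {
    FluorescenceTrace(t, a + b * t, condition = "line")
}
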