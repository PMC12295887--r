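# pevkactin

Titin's PEVK domain is a large intrinsically disordered segment of the
sarcomere's elastic filament. Although it lacks canonical actin-binding
motifs, it binds F-actin — and, at nanomolar concentrations, accelerates
the assembly of micromolar actin by seeding nucleation while leaving the
steady-state monomer/polymer balance (the critical concentration)
untouched. `pevkactin` packages the quantitative machinery for studying
this behaviour:

* **Kinetics.** An Oosawa-type nucleation–elongation simulator emulating
  the pyrene fluorescence assay. With monomer *m*, polymer *c<sub>f</sub>*,
  filament number *N* and nucleator *P*:

  dN/dt = k<sub>nuc</sub>·m<sup>n<sub>c</sub></sup> + k<sub>seed</sub>·P·m<sup>s<sub>c</sub></sup>  
  dc<sub>f</sub>/dt = n<sub>c</sub>·dN/dt + (k₊·m − k₋)·N,  m = A<sub>tot</sub> − c<sub>f</sub>

  so the critical concentration is analytically C<sub>c</sub> = k₋/k₊,
  independent of nucleation. The observation layer adds gain, baseline,
  photobleaching under continuous or intermittent illumination, and
  seeded Gaussian noise.
* **Trace quantitation.** Initial (0–40 s) and half-maximal assembly
  rates with linear-fit standard errors, peak intensity and time to peak,
  fold changes, and pre/post slope ratios around mid-run nucleator
  additions.
* **Critical concentration.** The classical steady-state pyrene
  construction — a least-squares line through the rising limb of the
  steady-state intensity vs. actin relation, intersected with the blank
  level — with residual-bootstrap confidence intervals and a paired
  comparison of two conditions.
* **Polymer geometry.** Worm-like-chain calculations for the disordered
  domain: L<sub>c</sub> = n·0.38 nm, R = √(L<sub>c</sub>L<sub>p</sub>),
  R<sub>G</sub> = R/√6, and the hexagonal sarcomere-lattice reach
  construction (thick-to-thin distance 2d₁₀/3).
* **AFM image analysis.** Synthetic 512×512 height images of nematic
  filament paracrystals and radial asters, 2D-FFT amplitude spectra,
  directional (sector-averaged) spectra, and robust spectral peak
  detection in the 5×10⁶–75×10⁶ m⁻¹ band.

Everything is S4 with validity checking; see the methods vignette
(`vignettes/pevk-actin-methods.Rmd`) for the models, parameter defaults
and numerical decisions.

## Worked example

```r
library(pevkactin)

## polymerize 4 uM actin (10% labeled) with 32.5 nM nucleator
params <- KineticParams(nucleatorConc = 32.5)
st <- simulatePolymerization(params, seq(0, 2000, by = 5))
st
#> KineticState: 401 time points over 2000 s
#>   final monomer 0.1206 uM, polymer 3.879 uM, filaments 0.002237 uM

## observe it through the pyrene model and quantify the trace
tr <- observeFluorescence(st, ObservationParams(noiseSd = 2, seed = 1))
quantifyTrace(tr)
#> TraceMetrics:
#>   initial rate  1.174 +/- 0.11 au/s
#>   halfmax rate  2.302 +/- 0.045 au/s
#>   peak          393.1 au at t = 345 s

## steady-state series at 60 nM nucleator, intermittent illumination
base <- KineticParams(kMinus = 1.392, nucleatorConc = 60)   # Cc = 0.12 uM
obs <- ObservationParams(noiseSd = 2, seed = 8,
                         schedule = IlluminationSchedule("intermittent"))
s <- simulateCcSeries(base, c(0.05, 0.1, 0.2, 0.4, 0.8, 1.2, 1.6, 2.0),
                      tEnd = 8000, obs = obs)
fitCc(s, bootstrapN = 500, seed = 9, baseline = 20, noiseSd = 2)
#> CcFit 'nucleator_60_nM': Cc = 0.1328 uM (95% CI 0.1123..0.151), slope 100.3 au/uM, 6 points

## worm-like-chain geometry of the full 2174-residue PEVK domain
chainGeometry(2174, persistenceLength = 1)
#> ChainGeometry: 2174 residues x 0.38 nm
#>   Lc = 826 nm, Lp = 1 nm, R = 28.7 nm, RG = 11.7 nm  (3 s.f.)

## paracrystal lattice spacing from a synthetic AFM image
img <- renderParacrystal(paracrystalSpec(noiseSd = 0))
detectPeriodicities(directionalSpectrum(fftAmplitude(img), angle = 90))
#> PeriodicityResult: periodicity detected (band 5e+06..7.5e+07 /m, probe 90 deg)
#>   13.3 nm (SF 7.52e+07 /m, amplitude 3.68e+03)
```

The final monomer concentration equals k₋/k₊ = 0.121 µM, the fitted
critical concentration recovers the configured 0.12 µM within its
bootstrap interval, and the directional FFT recovers the planted 13.3 nm
inter-filament spacing.

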