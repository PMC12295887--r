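---
title: "Models and methods behind pevkactin"
author: "pevkactin maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pevkactin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pevkactin)
```

# Scope

`pevkactin` studies how a nanomolar nucleator -- titin's intrinsically
disordered, glutamate-rich PEVK domain -- modulates the assembly of
micromolar actin.  The experimental readout it emulates is the pyrene
assay: pyrene-labeled actin fluoresces more strongly once incorporated
into filaments, so intensity tracks the F-actin amount over time.  The
package provides five coordinated pieces:

1. a nucleation--elongation simulator producing polymerization
   trajectories and pyrene-like fluorescence traces,
2. trace quantitation (initial rate, half-maximal rate, peak intensity,
   time to peak, fold changes, responses to mid-run nucleator addition),
3. critical-concentration estimation from steady-state
   intensity-versus-actin series, with bootstrap inference,
4. worm-like-chain geometry of the PEVK domain and its reach within the
   sarcomeric filament lattice, and
5. synthesis of AFM-like height images of filament fields (nematic
   paracrystals versus radial asters) and 2D-FFT periodicity detection.

# The kinetic model

The assay quantifies but does not itself prescribe a kinetic scheme, so
the simulator adopts the minimal Oosawa-type nucleation--elongation
model.  With free monomer $m$, polymerized actin $c_f$, filament number
concentration $N$ and nucleator concentration $P$:

$$\frac{dN}{dt} = k_{nuc}\, m^{n_c} + k_{seed}\, P\, m^{s_c}$$

$$\frac{dc_f}{dt} = n_c \frac{dN}{dt} + (k_+ m - k_-)\, N,
\qquad m = A_{tot} - c_f.$$

The first term of $dc_f/dt$ books the mass of each new nucleus
($n_c$ monomers) into the polymer pool at creation; together with
computing $m$ by difference this makes mass conservation exact by
construction.  The second term is reversible barbed-end elongation, whose
fixed point $m^\ast = k_-/k_+$ is the critical concentration $C_c$ --
crucially independent of both nucleation pathways.  That independence is
the model's restatement of the central experimental observation: seeding
accelerates early assembly dramatically while leaving the steady state
untouched.

Net depolymerization is gated smoothly to zero as $c_f \to 0$ (scale
$10^{-6}\,\mu M$, far below any observable signal), which keeps the
below-$C_c$ regime -- where nuclei form and immediately dissolve --
integrable without affecting any quantity the package reports.

## Parameter defaults and why

| parameter | default | units | rationale |
|---|---|---|---|
| $k_+$ | 11.6 | per uM per s | literature-typical barbed-end association |
| $k_-$ | 1.4 | per s | gives $C_c = 0.121$ uM, in the classical range |
| $n_c$ | 3 | monomers | smallest nucleus giving a clear lag phase |
| $k_{nuc}$ | 7.5e-9 | per uM^2 per s | see below |
| $s_c$ | 1 | -- | first order in monomer for seeded nucleation |
| $k_{seed}$ | 1e-7 | per nM per uM per s | see below |
| actin | 4 | uM | standard assay composition |
| labeled fraction | 0.1 | -- | standard assay composition |

$k_{nuc}$ and $k_{seed}$ are free choices of the generator, fixed once:
$k_{nuc}$ so that 4 uM actin self-assembles with a visible lag and
reaches steady state within the 2000 s assay window (half-assembly at
roughly 600 s), and $k_{seed}$ so that tens of nanomolar nucleator
dominates the spontaneous pathway by one to two orders of magnitude --
reproducing the observed behaviour that a nucleator three orders of
magnitude more dilute than actin raises the initial assembly rate by
tens-fold.  With these defaults the simulated dose series over
3.25--32.5 nM spans roughly a 3- to 26-fold initial-rate enhancement and
time-to-peak shortens several-fold, mirroring the assay's qualitative
pattern.

The nucleator acts catalytically ($P$ constant after addition); whether
PEVK seeds are consumed is unknown, and a consumed-seed variant would
only rescale $k_{seed}$ at these concentrations.  Additions are
instantaneous concentration steps with no mixing dead time.

Integration uses `deSolve::ode` (lsoda) at relative tolerance $10^{-8}$,
absolute $10^{-10}$, sampled onto the user grid; solver failure raises an
error rather than returning clipped values.

## The observation model

$$F(t) = \text{baseline} + \text{gain} \cdot f_{lab} \cdot c_f(t) \cdot
e^{-k_{bleach} E(t)} + \varepsilon(t)$$

where $E(t)$ is the cumulative *illuminated* exposure.  Under continuous
illumination $E(t) = t$; under the intermittent schedule (default: a 10 s
reading every 600 s, i.e. one measurement every 10 minutes) exposure
accrues only during the measurement windows and samples are emitted only
at illuminated times.  This reproduces both the slow post-peak intensity
decay seen in long continuously illuminated runs and the photobleaching
mitigation that intermittent reading provides in 8000 s steady-state
series.  Noise is independent Gaussian per sample; seeds are explicit,
and multi-trace drivers give trace $i$ the seed `seed + i - 1`.

# Trace quantitation

All slopes are ordinary least squares with the fit's standard error.
Defaults follow the assay's presentation: the initial rate over 0--40 s;
the half-maximal rate over an adaptive window $t_{1/2} \pm 30$ s, where
$t_{1/2}$ is the first crossing of
$\text{baseline} + (\text{peak}-\text{baseline})/2$, with the baseline
taken as the mean of the first three samples (a fixed 70--130 s window
can be supplied instead); the peak on a 5-sample moving average with
first-attainment tie-breaking; no bleach correction before metric
extraction (raw intensities are reported).  Slope operators are exactly
linear in the intensity scale and invariant to samples outside their
windows; both properties are tested.

One caveat worth knowing: over a symmetric window around a sigmoid's
midpoint, the OLS slope is a *centrally weighted* mean of the derivative,
so it sits between the end-to-end secant and the midpoint derivative
(about 18% above the secant for a logistic probed at $\pm 3$ time
constants).  Comparisons against "mean rate" numbers computed as secants
should expect that bias.

# Critical-concentration estimation

Above $C_c$ the steady-state polymer is $A_{tot} - C_c$, so steady-state
intensity is affine in total actin and extrapolates back to the blank
level at $A_{tot} = C_c$.  `fitCc` fits a least-squares line through the
points whose intensity exceeds $\text{baseline} + 3\sigma$ and intersects
it with the blank level (floored at zero).  The noise scale $\sigma$ is
an explicit argument -- the analyst knows the instrument noise -- with a
conservative default of 0 (every point strictly above baseline is used);
without a supplied blank, intensities are assumed blank-subtracted and
the lowest-concentration point serves as the selection baseline.
Uncertainty comes from a residual bootstrap (default 1000 replicates,
95% percentile interval, widened if needed to contain the point
estimate).  `compareCc` bootstraps the difference of two estimates and
declares a shared $C_c$ when the interval covers zero.  On simulated
series with 1% noise the estimator recovers the analytic $C_c$ to well
within 0.03 uM, and across a >10-fold span of seeded initial rates the
fitted $C_c$ moves by less than 5% -- the steady-state invariance claim,
restated as a testable property.

# Worm-like-chain geometry

For an ideal (conformationally relaxed) chain: contour length
$L_c = n \times 0.38$ nm, end-to-end distance $R = \sqrt{L_c L_p}$ and
radius of gyration $R_G = R/\sqrt{6}$.  Note some texts write
$R = \sqrt{2 L_c L_p}$; the convention here is pinned by the package's
reference arithmetic ($L_c = 826$ nm, $L_p = 1$ nm $\Rightarrow R = 28.7$
nm $\Rightarrow R_G = 11.7$ nm, all reported to 3 significant figures
while slots keep full precision).

```{r geometry}
chainGeometry(2174, persistenceLength = 1)
```

`latticeReach` places the chain in the ideal vertebrate hexagonal
double-lattice, where thin filaments occupy trigonal positions and the
nearest thick-to-thin distance is $2 d_{10} / 3$ (24.9 nm at
$d_{10} = 37.4$ nm).  The reach margin $R_G - 2d_{10}/3$ is negative for
the relaxed full-length domain (11.7 vs 24.9 nm): this lattice
construction is the package's own interpretation of the cross-sectional
schematic, not a measured quantity, and is labelled as such in its
documentation.

# Synthetic AFM images and periodicity detection

`renderParacrystal` draws parallel Gaussian ridges (comb of spacing $d$,
ridge $\sigma = 4$ nm, height 6 nm -- plausible F-actin dimensions under
AFM tip broadening) across a 512 px field at 2 nm/px, so the 13.3 nm
lattice sits well above Nyquist; `renderRadial` draws sparse asters of
short ridges (lengths drawn below 1 um) around focal Gaussian globules,
the morphology attributed to nucleator-seeded growth.  Overlapping
features combine by maximum; Gaussian pixel noise is added last; all
randomness is seed-controlled.

`fftAmplitude` mean-subtracts, applies a 2D Hann window (leakage and DC
suppression; only peak positions, never absolute amplitudes, are treated
as comparable), and returns the centered amplitude spectrum with
per-meter frequency axes.  `directionalSpectrum` averages a
$\pm 10^\circ$ sector (and its point reflection) into radial-frequency
bins one DFT step wide, reporting empty bins as missing rather than
zero.  The sector width is a speckle/variance compromise: narrow sectors
leave single-direction speckle that mimics peaks, wide ones dilute a
true reflection.

`detectPeriodicities` flags local maxima in the 5e6--75e6 per-m band
whose topographic prominence exceeds 5 median absolute deviations of the
in-band profile.  Two numerical refinements matter:

* **Count-aware thresholds.**  A bin's amplitude is a mean over the
  Fourier pixels in its sector-annulus cell, and near the low band edge a
  cell holds only a handful of pixels, fluctuating far more than the
  band-wide MAD.  Each bin's threshold is therefore scaled by
  $\sqrt{K_{med}/K}$ of its pixel count, and a peak must also rise that
  far above the in-band *median* (a distinct peak stands above the
  continuum, not merely above its own neighbouring dips).  Without these
  the false-positive rate on featureless noise is 5--15%; with them it is
  at or below 1--2% while a genuine lattice reflection, typically two to
  three orders of magnitude above the continuum, is unaffected.
* **Half-bin band slack.**  Band membership is tested with half a
  frequency bin of slack: printed band limits are rounded values, and at
  512 px the 13.3 nm fundamental (75.19e6 per m) falls a quarter bin
  outside a literal 75e6 per-m cut-off.  The harmonic at 6.65 nm remains
  far outside the band and is never reported.

`detectLatticeSpacing` is the blind classification pipeline: it picks
the strongest in-band spectral pixel to choose the probe direction and
then runs the detector, using no knowledge of the true orientation.  At
default parameters it detects the lattice in 50/50 seeded paracrystal
images (random orientations) and reports no periodicity in 50/50 seeded
radial fields.

# What the generators do and do not emulate

The simulator reproduces the three kinetic phases (lag, log, steady
state), dose-dependent seeding, mid-run addition responses,
photobleaching and illumination scheduling.  It deliberately omits
filament length distributions, fragmentation and annealing, ATP
hydrolysis and nucleotide states, pointed-end kinetics and capping.  The
image synthesizer omits tip convolution, scanner drift and line noise,
helical substructure, and the long-range (up to 200 nm) positional order
real paracrystals can show -- only the inter-filament fundamental is a
designed-in feature.  Passing tests therefore demonstrate correctness of
the analysis chain under this model, not fidelity of the model to every
feature of real traces or topographs; in particular, real data show
large sample-to-sample variation that the generator represents only as
Gaussian observation noise.

# Problem sizes and numerical choices in the test suite

The suite runs trace simulations on 2--5 s grids over 400--10000 s spans,
steady-state series over 8000 s (the long-assay span), bootstraps of
100--500 replicates, and image batches of 50 seeded 512 px renders per
morphology -- sizes chosen so the full suite completes in about half a
minute while every statistical check retains comfortable margins.  Seeds
are fixed throughout; steady-state attainment is verified against a
$10^{-5}$ uM/s tolerance on $|dc_f/dt|$ and errors name the offending
concentration.
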