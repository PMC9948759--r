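---
title: "Quantifying microtubule dynamics, luminal localization and end structure with mtquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule dynamics, luminal localization and end structure with mtquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtquant)
```

mtquant implements the quantification pipelines used in in vitro
microtubule (MT) reconstitution studies of lumen-binding stabilizers:
kymograph-based dynamic-instability statistics, MINFLUX filament-width
measurement, single-molecule intensity stoichiometry, cryo-ET
protofilament flare geometry, and EB1 comet counting. Every pipeline has
a seeded synthetic-data generator with stored ground truth, so each stage
can be validated end to end without external data. This vignette explains
the models, the tunable parameters and the numerical choices; all numbers
shown are computed by the code in this document or asserted by the
package's tests.

## Dynamic instability as a three-state Markov chain

Plus-end dynamics are modelled as a continuous-time Markov chain over
growth, pause and shrinkage with exponential dwell times. Published
quantifications report transition *frequencies* (events per unit time in
the source state); a memoryless chain with those frequencies as rates is
the minimal model consistent with that reporting, which is why the
generator does not attempt non-exponential dwells. If dwell-time
distributions ever become the target, the chain would need a semi-Markov
extension; we note this rather than guessing a distribution.

Position integrates +v~g~ (growth), 0 (pause) and −v~s~ (shrinkage), and
is floored at 0, the stabilized seed. Two boundary behaviours are
provided: `"reflect"` (non-depolymerizable seed: the tip re-enters
growth, as with GMPCPP seeds) and `"stop"` (the seed itself disassembles;
used for seed-survival assays).

```{r dynamics-example}
cfg <- dynamicsConfig(vGrowth = 2, vShrink = 30,
                      rates = c(gs = 0.004, sg = 0.02,
                                gp = 0.01, pg = 0.01),
                      duration = 600, dt = 0.5)
traj <- simulateDynamics(cfg, seed = 1)
traj
```

### Event classification

`classifyEvents()` reproduces the manual-kymograph analysis conventions:
per-segment velocities between traced vertices (no regression over
pixels, because the input *is* the manual trace), a strict 0.24 µm/min
velocity cutoff (exactly 0.24 µm/min is a pause, "faster than" being
strict), and the standard inclusion filters — growth or shrinkage
excursions longer than 0.40 µm, pauses longer than 20 s.

Sub-threshold events are kept in the event table with `included = FALSE`
and absorbed into the *preceding* included event when the contiguous
timeline is built (`collapseEvents()`). Whether the original analyses
absorbed such events forward, backward, or dropped their time entirely is
not documented anywhere we could find; absorbing backward keeps the
timeline contiguous and the frequency denominators well defined, and is
our documented choice rather than a claim about anyone else's code.

### Transition frequencies

The frequency of an `s -> t` transition is the number of such transitions
divided by the total time spent in state `s` — the time the transition
"could have occurred". A `denominator = "total"` option divides by total
observation time instead, since published per-experiment pooling is
ambiguous on this point; both are exposed.

Two analysis choices matter when the analyzer is pointed at simulated
(or seed-anchored) data:

* **Boundary censoring.** With a stabilized seed, every shrinkage that
  runs into position 0 is forced back into growth by construction.
  Counting those re-entries as rescues would inflate the rescue frequency
  several-fold in regimes where most shrinkage episodes reach the seed.
  With `boundaryFloor = 0`, a shrinkage-to-growth switch at the floor is
  treated as a censored episode: its time stays in the denominator, no
  event enters the numerator. For memoryless dwells this censoring leaves
  the estimator unbiased. The tolerance for "at the floor" should cover
  one sampling interval of shrinkage (`vShrink/60 * dt`).
* **Filters off for noiseless traces.** The 0.40 µm / 20 s filters exist
  to suppress manual-tracing artifacts. Simulated trajectories have no
  such artifacts, and with mean growth excursions of a few µm the filters
  would absorb the ~15% of genuine events below threshold and bias the
  recovered frequencies; round-trip validation therefore runs with the
  filters disabled and the defaults are reserved for real traces.

Event statistics (growth rate, pause duration) are computed on included
events *as classified*, before absorption, so absorbed intervals do not
dilute event velocities. SEM uses the sample SD (denominator n−1)
throughout the package.

## MINFLUX analysis

### dcr unmixing and channel assignment

Two-channel MINFLUX data are split on the detector channel ratio (dcr) by
fitting a two-component 1D Gaussian mixture with EM. Initialization is
deterministic — split at the median, per-half means and SDs, equal
weights — so the fit has no random restarts and identical input yields
identical output; convergence is |Δ log-likelihood| < 1e−8 or 500
iterations. Channel 1 is dcr in [0, µ₁ + 0.5σ₁], channel 2 is
[µ₂ − 0.5σ₂, 1], both intervals closed at their finite endpoints;
anything between is unassigned and excluded from rendering. If the two
cutoffs overlap the mixture is unusable and the assignment errors rather
than guessing.

### Rendering and width measurement

`renderDensity()` bins localizations on a regular grid
(`floor((coord − origin)/voxel)`, 1 nm default in 2D, 4 nm in 3D; total
counts conserved). `extractCenterlines()` segments line-like structures:
Gaussian ridge enhancement at the expected filament width, a quantile
threshold, Zhang–Suen skeletonization, spur pruning, and ordering into a
polyline. Three parameters deserve comment:

* **Filter scale** defaults to 15 voxels, the apparent width of a
  luminally labeled filament at 1 nm voxels. For surface-labeled
  filaments the apparent width is roughly the lattice diameter plus the
  localization error (≈ 35 nm), and the scale should follow it — at the
  luminal scale the projected ring-edge profile stays bimodal after
  smoothing and the segmentation splits into two parallel stripes.
* **Threshold quantile** (default 0.98 of the filtered image) presumes
  sparse fields in which filaments occupy a few percent of the area, as
  in real acquisitions. The right mental model: the threshold should land
  near the apparent half-maximum, so the occupied fraction divided by two
  is a good quantile complement. For the synthetic single-filament fields
  used in validation (≈ 1000 nm wide), 0.98 suits the axial geometry and
  0.95 the wider surface geometry.
* **Centerline smoothing.** A raw skeleton follows local density noise,
  and a centerline that meanders with the noise biases perpendicular
  distances low on *both* sides of the profile. The skeleton path is
  therefore refit with a low-degree-of-freedom smoothing spline
  (transverse vs. longitudinal coordinate in the path's principal-axis
  frame, ~1 df per 300 nm), falling back to a moving average for short
  or hooked paths.

`filamentFWHM()` accumulates voxel intensities (or raw localizations) by
signed perpendicular distance to the centerline, excluding contributions
that project beyond the centerline's endpoints (end-flare
contamination), sums along the filament and reads the FWHM from the two
half-maximum crossings nearest the peak, each linearly interpolated
between bins. Counting noise biases the *peak* estimate up and hence the
FWHM down (≈ −5% for flat-topped ring profiles at 2000 localizations);
the profile is therefore smoothed with a 2-bin Gaussian kernel before
the crossings are located, and the reported FWHM removes the known
widening of the kernel and the bin by quadrature subtraction (exact for
Gaussian profiles, sub-percent for the ring profile). The
intensity-weighted profile (not a binarized segmentation) is used, since
the measurement is defined on signal intensities.

Validation targets are analytic: an axially labeled filament with
localization SD σ has a Gaussian cross-profile with
FWHM = 2√(2 ln 2)·σ (8.24 nm at σ = 3.5 nm); a surface-labeled filament
projects to a ring-edge (arcsine) profile on ±12.5 nm whose convolution
with the localization Gaussian is computed by direct quadrature in the
test suite's independent oracle (≈ 29.6 nm at σ = 3.5 nm). The simulated
2D surface geometry is the projected ring; full cylinder sampling with
finite σ~z~ is used when 3D output is requested, and 3D maps are
inspected via 800-nm maximum-intensity cross-section projections.

### Precision QC

Localization precision is estimated from fluorophore burst statistics:
every trace id with more than four successive localizations contributes
its per-axis sample SD, and the histogram of SDs (0.25 nm bins) is
summarized by its mode. With finite bursts the mode of the SD sampling
distribution sits slightly below σ (for bursts of n, at about
σ·√((n−2)/(n−1))), which the tests account for.

## Single-molecule stoichiometry

Single-fluorophore brightness is calibrated by a closed-form
maximum-likelihood lognormal fit on log intensities; the figure-style
histogram least-squares fit estimates the same model less stably, and
the modal value exp(µ − σ²) is identical. Molecule counts divide
integrated intensities by the mean single-fluorophore intensity, with
the 8-nm normalization (one αβ-tubulin layer) for per-dimer occupancy.

The accumulation time course is fitted with one-phase association
I(t) = I₀ + (plateau − I₀)(1 − e^(−kt)) by Levenberg–Marquardt least
squares. The generator draws, per trace, floor(plateau−1) late-arriving
molecules plus a Bernoulli fractional part (exact expectation, and
deterministic molecule numbers at integer plateaus), each delayed by an
Exp(k) time, so the expected molecule number follows the model exactly.

TIRF z-attenuation of filament-bound fluorophores (≈ 0.8 in typical
geometries) is an optional multiplicative correction in
`initialBindingRatio()`, off by default: it is an interpretation aid,
not a calibrated constant. The monomer call band defaults to [0.6, 1.3]
after correction.

Profile alignment fits each max-normalized profile with a Hill curve
(exponent bounded to [0.5, 8], fitted freely) and aligns at the
half-maximum effective time — which for the Hill form is the fitted K —
or at the midpoint of a generic logistic when `model = "sigmoid"`.
Profiles whose fit fails are excluded and reported, the rest are
interpolated to a common grid and averaged with SEM; AUC is the
trapezoidal integral of each normalized profile on its native grid.

## Protofilament flare geometry

Protofilament traces are analyzed in an MT frame whose axis is either
supplied, assumed along +z (the generator's frame), or fitted as the
principal axis of the points. The first deflection point is the first
trace point whose radial distance exceeds `latticeRadius + tol` *and
stays above it to the tip* — the sustained rule rejects transient noise
excursions. `tol` defaults to 1.5 nm; the axial coordinate of the
crossing is refined by linear interpolation between the bracketing
points, which removes the point-spacing quantization. With ~1 nm
digitization noise the shallow geometry of flare onset still leaves a
few nm of irreducible jitter in the deflection coordinate, which
inflates recovered raggedness by several percent at a true SD of 12 nm;
the round-trip tests budget for this.

Flare metrics follow the conventional discretization: arc length from
the deflection point to the tip; total curvature as the summed turning
angles between consecutive segments; terminal curvature as mean turning
per 8 nm of arc (the tubulin dimer spacing) over the final window.
Turning angles are second differences of the coordinates, so
uncorrelated digitization noise of ~1 nm at 4-nm point spacing swamps
the per-vertex signal (~2° of genuine turning against tens of degrees
of noise); curvature quantification therefore presumes smooth traces,
which manual spline-style digitization produces, and the round-trip
validation of curvature and length runs on noiseless generator output. The
window length is not documented in published analyses; 24 nm (three
dimers) is our configurable default. End raggedness is the sample SD
(n−1) of the deflection points' axial coordinates, undefined for fewer
than two protofilaments. Defect identification itself is visual
annotation, not computed: `latticeSummaries()` consumes annotation
tables and reports defects/µm and %ILP-positive per tomogram with
mean ± sample SD across tomograms.

## Comet counting

The counting pipeline is rolling-ball background subtraction (grayscale
opening with a non-flat hemispherical structuring element, radius 10 px
default; exact ImageJ pixel parity is not promised — correctness is
asserted against the morphological definition), Kapur maximum-entropy
thresholding (256 bins over the min–max range, validated against an
O(L²) brute-force oracle), 8-connected particle analysis (the ImageJ
default; 4-connectivity is available), an area cutoff of 0.10 µm², and
normalization to comets per 100 µm² of cell area. Cell segmentation is
out of scope; the cell area is an input.

The comet generator renders discs, not elongated comets: the pipeline
thresholds on area, for which elongation is irrelevant.

## What the synthetic generators do and do not emulate

The generators reproduce the statistical structure each analysis stage
sees: state-switching trajectories with exact velocities, localization
scatter with per-axis Gaussian error and a two-component dcr mixture,
lognormal brightness with stepwise arrivals, flares with controllable
kink spread and curvature, and discs on uneven background. They do not
emulate photophysics (blinking, bleaching), EB-comet intensity profiles,
drift, detector gain, missing-wedge effects, or manual-tracing error
models. Passing round-trip tests therefore demonstrates that the
analysis code measures what it claims on data of known structure — not
that every acquisition artifact of real microscopy is handled.

## Problem sizes and determinism

Validation uses 200 simulated MTs × 600 s for dynamics, 50 filaments ×
2000 localizations per labeling mode for widths, 300 traces for
kinetics, 100 ends × 13 protofilaments for raggedness, and 35-blob
images for counting — sizes at which Monte-Carlo error sits comfortably
inside the asserted tolerances. All generators take an explicit seed,
restore the caller's RNG state, and record the seed in their output
metadata.
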