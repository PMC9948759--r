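# mtquant

Quantification toolkit for in vitro microtubule (MT) reconstitution
experiments, written for studies of proteins that stabilize microtubules
from the lumen. It covers the five quantification tasks such studies
combine, each exposed as plain R functions over S4 data containers and
each paired with a seeded synthetic-data generator with known ground
truth:

1. **Kymograph dynamics** — classify traced tip trajectories into
   growth / pause / shrinkage events (strict 0.24 µm/min velocity cutoff;
   0.40 µm and 20 s inclusion filters) and compute growth rates, pause
   durations, state time fractions and the six transition frequencies
   (events per second of source-state time). Dynamic instability is
   simulated as a three-state continuous-time Markov chain for round-trip
   validation.
2. **MINFLUX filament widths** — detector-channel-ratio (dcr) unmixing by
   a deterministic two-component Gaussian EM with the
   `[0, µ1 + 0.5σ1]` / `[µ2 − 0.5σ2, 1]` channel cutoffs, density-map
   rendering, centerline extraction (ridge filter → threshold →
   skeletonization), and filament width as the FWHM of the perpendicular
   intensity profile summed along the filament. A luminal label at
   localization error σ gives FWHM `2·sqrt(2·ln 2)·σ`; a surface label on
   the 12.5-nm lattice radius gives the projected ring-edge profile
   convolved with the localization error.
3. **Single-molecule stoichiometry** — closed-form maximum-likelihood
   lognormal calibration of single-fluorophore brightness (mode
   `exp(µ − σ²)`), molecules per 8 nm of accumulation, one-phase
   association kinetics `I(t) = I0 + (plateau − I0)(1 − e^(−kt))`, and
   alignment of intensity profiles at the half-maximum times of Hill
   fits, with AUC.
4. **Protofilament flare geometry** — first deflection points (sustained
   radial excess beyond the lattice cylinder), flare arc length, total
   and terminal curvature (degrees per 8 nm of arc), end raggedness (the
   sample SD of deflection points' axial coordinates), and per-tomogram
   defect-density / %ILP summaries from annotation tables.
5. **Comet counting** — rolling-ball background subtraction (grayscale
   opening with a non-flat ball, radius 10 px), Kapur maximum-entropy
   thresholding, 8-connected particle analysis with a 0.10 µm² area
   cutoff, normalized to comets per 100 µm².

## Worked example

Simulate fifty dynamic microtubules, recover their dynamics parameters,
and measure the width of a luminally labeled filament from simulated
MINFLUX localizations:

```r
library(mtquant)

cfg <- dynamicsConfig(vGrowth = 2, vShrink = 30,
                      rates = c(gs = 0.004, sg = 0.02,
                                gp = 0.01, pg = 0.01),
                      duration = 600, dt = 0.5)
thr0 <- dynamicsThresholds(minGrowthLength = 1e-9, minPauseDuration = 1e-9)
events <- lapply(1:50, function(i)
  classifyEvents(simulateDynamics(cfg, seed = i), thresholds = thr0))
summ <- summarizeDynamics(events, boundaryFloor = 0)
tf <- transitionFrequencies(events, boundaryFloor = 0, boundaryTol = 0.3)

tab <- simulateMinflux(filamentSpec(labelingMode = "axial", sigmaXY = 3.5,
                                    nLocalizations = 2000), seed = 1)
map <- renderDensity(tab, voxelSize = 1, origin = c(-30, -500),
                     fieldDim = c(1060, 1000))
cl <- extractCenterlines(map, minLength = 300)[[1]]
prof <- filamentFWHM(map, cl)

cat(sprintf("growth rate: %.2f +/- %.3f um/min (n = %d events, %d MTs)\n",
            summ$growthRate$mean, summ$growthRate$sem,
            summ$growthRate$n, summ$nMTs))
cat(sprintf("catastrophe frequency: %.5f per s (%d events)\n",
            tf$frequencies["growth_shrinkage"],
            tf$counts["growth_shrinkage"]))
cat(sprintf("state fractions (g/p/s): %.2f / %.2f / %.2f\n",
            summ$stateFractions["growth"], summ$stateFractions["pause"],
            summ$stateFractions["shrinkage"]))
cat(sprintf("filament FWHM: %.2f nm (length %.0f nm; theory 8.24 nm)\n",
            prof$fwhm, prof$filamentLength))
```

This prints:

```
growth rate: 1.96 +/- 0.007 um/min (n = 251 events, 50 MTs)
catastrophe frequency: 0.00345 per s (57 events)
state fractions (g/p/s): 0.55 / 0.43 / 0.01
filament FWHM: 8.42 nm (length 859 nm; theory 8.24 nm)
```

The recovered growth rate matches the configured 2 µm/min within 2%, the
catastrophe frequency estimate (0.00345/s from 57 events) is within
sampling error of the configured 0.004/s, and the measured width of an
axially labeled filament matches the closed form `2·sqrt(2·ln 2)·3.5 =
8.24 nm` within a few percent — the separation that lets rendered MINFLUX
images discriminate luminal from surface labeling. The sub-threshold
event filters are disabled here because simulated traces carry no tracing
artifacts, and `boundaryFloor = 0` censors forced re-entries at the
stabilized seed so they are not scored as rescues (see the methods
vignette, `vignettes/mtquant-methods.Rmd`).

## Data interchange

CSV readers/writers are provided for every input and output type
(tip-trace, localization, protofilament and annotation tables), plus
32-bit float TIFF export for rendered density maps and images; see
`?readTipTrajectories`, `?readLocalizations`, `?readProtofilaments`,
`?readLatticeAnnotations`, `?writeImageTiff`.
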