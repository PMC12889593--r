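# microcapKP

Quantifies how much of a nanoscale tracer accumulates inside synthetic
biofilm analogs — hemispherical nanocellulose hydrogel "microcaps" on a
reflective polycarbonate coupon — from three-channel confocal z-stacks. It
is written for experimenters studying nanomaterial transport barriers
(size exclusion by the hydrated mesh, volume exclusion by embedded
microspheres, electrostatic attachment) and for ecotoxicologists who need
the results on the bioconcentration-factor scale.

The core quantity is the **microcap partition coefficient**

```
K_P = [FITC]_microcap / [FITC]_water
```

the mean FITC-nanodextran intensity over the microcap interior (hydrogel ∪
microsphere voxels) divided by the mean in the surrounding water. The
package provides, end to end:

* **Phantoms** (`makeGeometry`, `renderStack`, `groundTruth`) — synthetic
  microcap z-stacks with exact voxel labels and a known true K_P, so every
  downstream stage is testable without raw microscope data.
* **Segmentation** (`segmentStack` and friends) — four-domain assignment
  (water / hydrogel / microsphere / coupon) via Otsu thresholding, per-slice
  region filling of the unstained hydrogel core, small-region discard, and a
  z-direction coupon edge detector biased toward the coupon.
* **Quantification** (`partitionCoefficient`, `equilibriumReached`) —
  per-domain FITC means, K_P, and the time-lapse plateau check.
* **Statistics** (`runHypothesisBattery`) — technical-replicate averaging
  (3 microcaps/coupon), batch samples of n = 3, Shapiro–Wilk gating, and six
  one-tailed Welch tests at α = 0.05 covering the size-exclusion,
  volume-exclusion and attachment hypotheses.
* **Ecotox conversions** (`kpToPbcf`, `dryToWetBcf`, `poreCorrectedBcf`,
  `buildComparisonTable`) — the pBCF = −log10(K_P) scale, the 100:1 wet/dry
  rescale, the pore-water correction Δ pBCF = log10(1 + m_w/m_b), and a
  merged comparison table against a shipped literature fixture.
* **Design** (`studyPlan`, `enumeratePlan`, `simulateStudy`) — the
  11-condition replicate hierarchy (12 hydrogels, 33 coupons, 99 microcaps)
  and fast/full-mode synthetic dataset generation.

## Worked example

```r
library(microcapKP)

# A 64^3 phantom with true KP = 0.7 and Poisson-Gaussian camera noise
geom <- makeGeometry(capRadius = 24, couponZ = 2, seed = 1)
cfg  <- imagingConfig(dim = c(64, 64, 64), voxelSize = 1,
                      noiseModel = noisePoissonGaussian(gain = 1, sd = 10),
                      seed = 1)
fld  <- concentrationField(fitcWater = 100, fitcHydrogel = 70,
                           fitcMicrosphere = 70)
groundTruth(geom, cfg, fld)$trueKp
#> [1] 0.7
stk <- renderStack(geom, fld, cfg)
seg <- segmentStack(stk)
#> Warning: AF594 channel shows no sparse microsphere signal ... returning an
#> empty microsphere mask   (expected: this phantom carries no spheres)
partitionCoefficient(channel(stk, "fitc"), seg)
#> PartitionResult
#>   [FITC]microcap = 69.97, [FITC]water = 100
#>   KP = 0.6998
```

The recovered KP (0.6998) agrees with the constructed truth (0.7) to well
under a percent; noise-free rendering recovers it exactly.

```r
# The simulated study and its hypothesis battery
ds <- simulateStudy(studyPlan(), studyEffectKp(), seed = 1)
runHypothesisBattery(ds)[, c("effect", "condition_a", "condition_b", "t", "p")]
#>             effect       condition_a       condition_b         t            p
#> 1   size_exclusion      plain/Dx-150     plain/Dx-2000 15.095539 0.0003514877
#> 2 volume_exclusion       none/Dx-150      plain/Dx-150  1.800894 0.0733470641
#> 3       attachment      amino/CM-150      plain/CM-150  8.348995 0.0026825651
#> 4       attachment      amino/CM-150      amino/Dx-150  4.665935 0.0049298023
#> 5       attachment carboxyl/DEAE-150   plain/DEAE-150  -6.787754 0.9979462451
#> 6       attachment carboxyl/DEAE-150  carboxyl/Dx-150  -4.573869 0.9888176054
```

Row 1 is the size-exclusion contrast: the 2 MDa dextran partitions ~30 %
lower than the 150 kDa dextran (true condition KPs 0.480 vs 0.685), and the
one-tailed Welch test detects it. The p-values near 1 are directional tests
whose effect points the other way in this simulated world.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it enumerates the study design, simulates the full 99-microcap dataset and
runs the Welch battery, renders/segments/quantifies a noisy phantom to
recover a known K_P, builds the merged bioconcentration table, and evaluates
the pore-water factor. Run it from the repository root against the installed
package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Progress goes to stderr; the JSON result object is written to `--out`.

See `vignettes/microcap-partitioning.Rmd` for the model, parameter defaults,
calibration analysis and known limitations.
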