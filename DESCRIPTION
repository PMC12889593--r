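Package: microcapKP
Title: Partition-Coefficient Quantification of Nanomaterial Accumulation in
    Synthetic Biofilm Microcaps
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying nanomaterial accumulation in synthetic
    biofilm analogs ("microcaps": hemispherical nanocellulose hydrogel domes
    on a reflective coupon) from three-channel confocal z-stacks. Provides a
    synthetic phantom generator with exact ground-truth voxel labels and a
    known true partition coefficient; four-domain segmentation (water,
    hydrogel, microsphere, coupon) via Otsu thresholding, per-slice region
    filling, small-region discard and a z-direction coupon edge detector;
    microcap partition-coefficient (KP) quantification with an equilibrium
    plateau check; the replicate-aware one-tailed Welch hypothesis battery for
    size-exclusion, volume-exclusion and attachment effects with Shapiro-Wilk
    normality gating; and ecotoxicological bioconcentration-factor (BCF/pBCF)
    conversions including the pore-water correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
biocViews: Software, ImageSegmentation, Visualization, StatisticalMethod
RoxygenNote: 7.3.3
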