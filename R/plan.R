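## The experimental design: 4 hydrogel types (by embedded microsphere) x the
## nanodextrans tested against each, 3 hydrogel batches per type, one coupon
## per (batch x nanodextran), 3 microcap technical replicates per coupon.
## The study plan reproduces the printed totals: 12 hydrogels, 33 coupons,
## 99 microcaps across 11 conditions.

#' ExperimentPlan: replicate hierarchy of a microcap study
#'
#' @slot hydrogelTypes character, microsphere loading of each hydrogel type.
#' @slot batchesPerType integer(1), hydrogel batches per type.
#' @slot nanodextransPerType named list mapping each hydrogel type to the
#'   nanodextrans tested against it.
#' @slot microcapsPerCoupon integer(1), technical replicates per coupon.
#' @seealso [studyPlan()], [enumeratePlan()]
#' @export
setClass("ExperimentPlan",
  representation(hydrogelTypes = "character", batchesPerType = "integer",
                 nanodextransPerType = "list", microcapsPerCoupon = "integer")
)

setValidity("ExperimentPlan", function(object) {
  msg <- character()
  if (!length(object@hydrogelTypes)) msg <- c(msg, "no hydrogel types")
  if (!setequal(names(object@nanodextransPerType), object@hydrogelTypes))
    msg <- c(msg, "nanodextransPerType must be named by hydrogelTypes")
  if (object@batchesPerType < 1L) msg <- c(msg, "batchesPerType must be >= 1")
  if (object@microcapsPerCoupon < 1L)
    msg <- c(msg, "microcapsPerCoupon must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExperimentPlan", function(object) {
  e <- enumeratePlan(object)
  cat("ExperimentPlan:", length(object@hydrogelTypes), "hydrogel types,",
      object@batchesPerType, "batches each,",
      object@microcapsPerCoupon, "microcaps/coupon\n")
  cat(sprintf("  totals: %d hydrogels, %d coupons, %d microcaps (%d conditions)\n",
              e$hydrogels, e$coupons, e$microcaps,
              nrow(unique(e$conditions[c("microsphere_type", "nanodextran")]))))
})

#' The study's experiment plan
#'
#' Reconstructed from the 11 tested microsphere-type x nanodextran
#' combinations: microsphere-free hydrogels were tested only with the neutral
#' 150 kDa dextran; plain-microsphere hydrogels with all four dextrans
#' (Dx-150, Dx-2000, DEAE-150, CM-150); charged-microsphere hydrogels with
#' the three 150 kDa dextrans. With 3 batches per type and 3 microcaps per
#' coupon this reproduces all three printed totals (12 hydrogels, 33 coupons,
#' 99 microcaps) simultaneously.
#'
#' @param batchesPerType hydrogel batches per type (default 3).
#' @param microcapsPerCoupon technical replicates per coupon (default 3).
#' @return An [ExperimentPlan-class].
#' @examples
#' enumeratePlan(studyPlan())[c("hydrogels", "coupons", "microcaps")]
#' @export
studyPlan <- function(batchesPerType = 3L, microcapsPerCoupon = 3L) {
  new("ExperimentPlan",
      hydrogelTypes = c("none", "plain", "carboxyl", "amino"),
      batchesPerType = as.integer(batchesPerType),
      nanodextransPerType = list(
        none = "Dx-150",
        plain = c("Dx-150", "Dx-2000", "DEAE-150", "CM-150"),
        carboxyl = c("Dx-150", "DEAE-150", "CM-150"),
        amino = c("Dx-150", "DEAE-150", "CM-150")),
      microcapsPerCoupon = as.integer(microcapsPerCoupon))
}

#' Nanodextran characterization metadata
#'
#' Size and charge metadata of the four tracers (NTA/DLS sizes in nm, zeta
#' potential in mV); metadata only, never used numerically.
#'
#' @return data.frame with one row per nanodextran.
#' @export
nanodextranSpecs <- function() {
  data.frame(
    name = c("Dx-150", "DEAE-150", "CM-150", "Dx-2000"),
    molecular_weight_kDa = c(150, 150, 150, 2000),
    charge = c("neutral", "positive", "negative", "neutral"),
    nta_size_nm = c(226, 178, 173, 301.5),
    dls_size_nm = c(115, 107, 771, 81),
    zeta_mV = c(-1.2, -0.4, -5.7, -2.4),
    stringsAsFactors = FALSE
  )
}

#' Enumerate an experiment plan
#'
#' Hydrogels = types x batches; coupons = sum over types of
#' batches x number of nanodextrans; microcaps = coupons x microcaps per
#' coupon.
#'
#' @param plan an [ExperimentPlan-class].
#' @return list with `hydrogels`, `coupons`, `microcaps`, and `conditions`, a
#'   flat coupon-level table (`microsphere_type`, `nanodextran`, `batch`,
#'   `coupon`).
#' @export
enumeratePlan <- function(plan) {
  validObject(plan)
  rows <- list()
  couponId <- 0L
  for (ty in plan@hydrogelTypes) {
    for (b in seq_len(plan@batchesPerType)) {
      for (nd in plan@nanodextransPerType[[ty]]) {
        couponId <- couponId + 1L
        rows[[couponId]] <- data.frame(
          microsphere_type = ty, nanodextran = nd, batch = b,
          coupon = couponId, stringsAsFactors = FALSE)
      }
    }
  }
  conditions <- do.call(rbind, rows)
  list(hydrogels = length(plan@hydrogelTypes) * plan@batchesPerType,
       coupons = nrow(conditions),
       microcaps = nrow(conditions) * plan@microcapsPerCoupon,
       conditions = conditions)
}

#' True condition KPs for the study scenario
#'
#' The generator's stated world: the true partition coefficient of each of
#' the 11 conditions, taken from the study's printed pBCF rows via
#' `kp = 10^(-pbcf)` (so, e.g., plain/Dx-150 has true KP ~ 0.685 and
#' plain/Dx-2000 ~ 0.480 — the ~30 percent size-exclusion decrease).
#'
#' @return Named numeric vector keyed by `"<microsphere_type>/<nanodextran>"`.
#' @export
studyEffectKp <- function() {
  path <- system.file("extdata", "study_pbcf.csv", package = "microcapKP",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(pbcfToKp(df$pbcf),
                  paste(df$microsphere_type, df$nanodextran, sep = "/"))
}

#' Simulate a full study dataset
#'
#' Fast mode (default) draws each microcap's KP directly:
#' `kp = trueKp * (1 + e)` with `e ~ N(0, noiseSd)` (truncated at zero) —
#' appropriate for statistical calibration. Full mode renders a phantom
#' z-stack per microcap (hydrogel and microsphere FITC set so the true KP is
#' exact), runs the segmentation pipeline and quantifies KP end to end —
#' appropriate for integration tests, and much slower.
#'
#' @param plan an [ExperimentPlan-class].
#' @param trueKp named numeric of true KP per `"<type>/<nanodextran>"`
#'   condition; every condition in the plan must be present.
#' @param noiseSd relative KP noise per microcap (default 0.05, the
#'   batch-level coefficient of variation the power analysis assumes).
#' @param seed RNG seed; fixed seed gives a bit-reproducible dataset.
#' @param mode `"fast"` or `"full"`.
#' @param fullConfig list of rendering knobs for full mode: `dimVox` (cube
#'   edge, default 64), `capRadius` (um, default 24), `fitcWater` (default
#'   100), `noise` (an [imagingConfig()] noise model; default
#'   Poisson-Gaussian with sd 10 percent of the water signal), `nSpheres`
#'   (default 0).
#' @return data.frame with one row per microcap: `microsphere_type`,
#'   `nanodextran`, `batch`, `coupon`, `microcap`, `kp`.
#' @examples
#' ds <- simulateStudy(studyPlan(), studyEffectKp(), seed = 1)
#' nrow(ds)  # 99
#' @export
simulateStudy <- function(plan, trueKp, noiseSd = 0.05, seed = 1L,
                          mode = c("fast", "full"), fullConfig = list()) {
  mode <- match.arg(mode)
  enum <- enumeratePlan(plan)
  cond <- enum$conditions
  key <- paste(cond$microsphere_type, cond$nanodextran, sep = "/")
  missing <- setdiff(unique(key), names(trueKp))
  if (length(missing))
    stop("missing true KP for condition(s): ", paste(missing, collapse = ", "))
  nCap <- plan@microcapsPerCoupon
  rows <- cond[rep(seq_len(nrow(cond)), each = nCap), ]
  rows$microcap <- rep(seq_len(nCap), times = nrow(cond))
  rows$true_kp <- trueKp[paste(rows$microsphere_type, rows$nanodextran,
                               sep = "/")]
  rownames(rows) <- NULL

  if (mode == "fast") {
    rows$kp <- withSeed(seed, {
      pmax(rows$true_kp * (1 + rnorm(nrow(rows), 0, noiseSd)), 0)
    })
  } else {
    fc <- utils::modifyList(list(dimVox = 64L, capRadius = 24, fitcWater = 100,
                                 noise = NULL, nSpheres = 0L), fullConfig)
    if (is.null(fc$noise))
      fc$noise <- noisePoissonGaussian(gain = 1, sd = 0.1 * fc$fitcWater)
    targets <- withSeed(seed, {
      pmax(rows$true_kp * (1 + rnorm(nrow(rows), 0, noiseSd)), 0)
    })
    rows$kp <- vapply(seq_len(nrow(rows)), function(i) {
      capSeed <- (seed * 7919L + i * 104729L) %% 2147483647L
      recoverPhantomKp(targets[i], dimVox = fc$dimVox,
                       capRadius = fc$capRadius, fitcWater = fc$fitcWater,
                       noise = fc$noise, nSpheres = fc$nSpheres,
                       seed = capSeed)
    }, numeric(1))
  }
  rows$true_kp <- NULL
  rows
}

#' Render one phantom at a target KP and recover KP through the pipeline
#'
#' Builds a hemispherical phantom whose hydrogel and microsphere FITC levels
#' are `kpTrue * fitcWater` (so the true partition coefficient is exactly
#' `kpTrue`), renders it with the given noise model, segments it with
#' [segmentStack()] and quantifies with [partitionCoefficient()].
#'
#' @param kpTrue target true KP.
#' @param dimVox cube edge in voxels (isotropic 1 um grid).
#' @param capRadius cap radius in um.
#' @param fitcWater water FITC level.
#' @param noise a noise model (see [noiseNone()]).
#' @param nSpheres microspheres to embed.
#' @param seed RNG seed for placement and noise.
#' @param params segmentation parameters.
#' @return Recovered KP (numeric scalar).
#' @export
recoverPhantomKp <- function(kpTrue, dimVox = 64L, capRadius = 24,
                             fitcWater = 100, noise = noiseNone(),
                             nSpheres = 0L, seed = 1L,
                             params = segmentationParams()) {
  geom <- makeGeometry(capRadius = capRadius, couponZ = 2,
                       nSpheres = nSpheres, seed = seed)
  cfg <- imagingConfig(dim = rep(as.integer(dimVox), 3L), voxelSize = 1,
                       noiseModel = noise, seed = seed)
  fld <- concentrationField(fitcWater = fitcWater,
                            fitcHydrogel = kpTrue * fitcWater,
                            fitcMicrosphere = kpTrue * fitcWater,
                            cwShell = 2 * fitcWater,
                            af594Sphere = 2 * fitcWater,
                            couponReflection = 3 * fitcWater)
  stk <- renderStack(geom, fld, cfg)
  seg <- suppressWarnings(segmentStack(stk, params))
  kpValue(partitionCoefficient(channel(stk, "fitc"), seg))
}
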