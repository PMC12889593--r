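#' @import methods
#' @importFrom stats rnorm rpois runif lm coef pt qt sd var setNames
#' @importFrom utils read.csv write.csv head
#' @useDynLib microcapKP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Domain label codes
#'
#' Integer codes used throughout the package for the four spatial domains of a
#' microcap image: the surrounding water (liquid domain), the hydrogel mesh
#' (interstitial domain), the embedded polystyrene microspheres, and the solid
#' polycarbonate coupon the cap rests on. The microcap domain proper is the
#' union hydrogel + microsphere.
#'
#' @format Named integer vector with entries `water = 0`, `hydrogel = 1`,
#'   `microsphere = 2`, `coupon = 3`.
#' @export
DOMAIN_CODES <- c(water = 0L, hydrogel = 1L, microsphere = 2L, coupon = 3L)

## ---------------------------------------------------------------------------
## Phantom-side value classes
## ---------------------------------------------------------------------------

#' MicrocapGeometry: analytic description of a synthetic microcap
#'
#' A hemispherical hydrogel cap of radius `capRadius` resting on the plane
#' `z = couponZ` (the coupon occupies all z at or below that plane), with
#' optional embedded spherical microspheres. All lengths are micrometers.
#'
#' @slot capCenter numeric(2), (x, y) position of the cap center on the coupon.
#' @slot capRadius numeric(1), cap radius; caps are imaged below 250 um
#'   diameter, so the default scenarios keep `2 * capRadius <= 250`.
#' @slot couponZ numeric(1), height of the coupon surface plane.
#' @slot spheres numeric matrix with columns `x`, `y`, `z`, `r`; one row per
#'   microsphere. Zero rows when the cap carries no spheres.
#' @slot cwPenetrationDepth numeric(1); the cellulose stain only penetrates
#'   ~10 um into the hydrogel, so only the outer shell of that thickness is
#'   stained.
#'
#' @seealso [makeGeometry()]
#' @export
setClass("MicrocapGeometry",
  representation(
    capCenter = "numeric",
    capRadius = "numeric",
    couponZ = "numeric",
    spheres = "matrix",
    cwPenetrationDepth = "numeric"
  )
)

setValidity("MicrocapGeometry", function(object) {
  msg <- character()
  if (length(object@capCenter) != 2L || any(!is.finite(object@capCenter)))
    msg <- c(msg, "capCenter must be a finite length-2 numeric (x, y)")
  if (length(object@capRadius) != 1L || !is.finite(object@capRadius) ||
      object@capRadius <= 0)
    msg <- c(msg, "capRadius must be a single positive number")
  if (length(object@couponZ) != 1L || !is.finite(object@couponZ))
    msg <- c(msg, "couponZ must be a single finite number")
  if (length(object@cwPenetrationDepth) != 1L ||
      object@cwPenetrationDepth <= 0)
    msg <- c(msg, "cwPenetrationDepth must be positive")
  sp <- object@spheres
  if (ncol(sp) != 4L) {
    msg <- c(msg, "spheres must have 4 columns (x, y, z, r)")
  } else if (nrow(sp) > 0L) {
    if (any(sp[, 4L] <= 0)) msg <- c(msg, "sphere radii must be positive")
    # every sphere entirely inside the hemisphere and above the coupon plane
    d <- sqrt((sp[, 1L] - object@capCenter[1L])^2 +
              (sp[, 2L] - object@capCenter[2L])^2 +
              (sp[, 3L] - object@couponZ)^2)
    if (any(d + sp[, 4L] > object@capRadius + 1e-9))
      msg <- c(msg, "every sphere must lie entirely inside the hemispherical cap")
    if (any(sp[, 3L] - sp[, 4L] < object@couponZ - 1e-9))
      msg <- c(msg, "every sphere must lie above the coupon plane")
    if (nrow(sp) > 1L) {
      dd <- as.matrix(stats::dist(sp[, 1:3, drop = FALSE]))
      rr <- outer(sp[, 4L], sp[, 4L], "+")
      diag(dd) <- Inf
      if (any(dd < rr - 1e-9))
        msg <- c(msg, "spheres must be pairwise non-overlapping")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ConcentrationField: equilibrium intensities per material
#'
#' The piecewise-constant fluorescence intensities used to render a phantom:
#' the FITC-nanodextran level in bulk water, in the hydrogel, and in the
#' microspheres (all in arbitrary detector units), the Calcofluor White shell
#' intensity, the AF594 microsphere intensity, and the additive FITC-channel
#' reflection at the coupon surface. Equilibrium concentrations are set, not
#' simulated: the generator states the end state of the accumulation phase.
#'
#' @slot fitcWater,fitcHydrogel,fitcMicrosphere numeric(1), FITC levels >= 0.
#' @slot cwShell numeric(1), CW intensity of the stained hydrogel shell.
#' @slot af594Sphere numeric(1), AF594 intensity inside microspheres.
#' @slot couponReflection numeric(1), FITC added in the single voxel layer at
#'   the coupon surface (the coupon reflects green light at its surface).
#' @seealso [concentrationField()], [trueKp()]
#' @export
setClass("ConcentrationField",
  representation(
    fitcWater = "numeric", fitcHydrogel = "numeric",
    fitcMicrosphere = "numeric", cwShell = "numeric",
    af594Sphere = "numeric", couponReflection = "numeric"
  )
)

setValidity("ConcentrationField", function(object) {
  v <- c(object@fitcWater, object@fitcHydrogel, object@fitcMicrosphere,
         object@cwShell, object@af594Sphere, object@couponReflection)
  if (length(v) != 6L || any(!is.finite(v)))
    return("all six intensities must be single finite numbers")
  if (any(v < 0)) return("intensities must be >= 0")
  TRUE
})

#' ImagingConfig: voxel grid, optics and noise for phantom rendering
#'
#' @slot dim integer(3), stack shape as `(nx, ny, nz)` voxels. Note R arrays
#'   are column-major with x fastest; volumes everywhere in this package are
#'   `array(dim = c(nx, ny, nz))`.
#' @slot voxelSize numeric(3), voxel edge lengths `(dx, dy, dz)` in um.
#' @slot noiseModel list with element `type` in `none`, `gaussian`,
#'   `poisson_gaussian`; `gaussian` takes `sd`, `poisson_gaussian` takes
#'   `gain` and `sd` (camera model: `gain * Poisson(I / gain) + N(0, sd)`,
#'   clamped at zero).
#' @slot blurSigma numeric(3), Gaussian blur sigma per axis in um; `c(0,0,0)`
#'   disables blur.
#' @slot seed integer(1), mandatory RNG seed; with `noiseModel$type = "none"`
#'   and blur off, rendering is deterministic and piecewise constant.
#' @seealso [imagingConfig()], [renderStack()]
#' @export
setClass("ImagingConfig",
  representation(
    dim = "integer", voxelSize = "numeric",
    noiseModel = "list", blurSigma = "numeric", seed = "integer"
  )
)

setValidity("ImagingConfig", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be three positive voxel counts (nx, ny, nz)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (um)")
  if (is.null(object@noiseModel$type) ||
      !object@noiseModel$type %in% c("none", "gaussian", "poisson_gaussian"))
    msg <- c(msg, "noiseModel$type must be none | gaussian | poisson_gaussian")
  if (length(object@blurSigma) != 3L || any(object@blurSigma < 0))
    msg <- c(msg, "blurSigma must be three non-negative sigmas (um)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Image-side classes
## ---------------------------------------------------------------------------

#' ChannelStack: a three-channel confocal z-stack
#'
#' The raw observable: three co-registered 3-D intensity volumes over one
#' voxel grid. Channels follow the acquisition design: Calcofluor White
#' (405 nm; hydrogel shell), AF594-like (561 nm; microspheres), and FITC
#' (488 nm; nanodextran everywhere plus the coupon reflection at its surface).
#'
#' @slot cw,af594,fitc numeric arrays `(nx, ny, nz)`, intensities >= 0.
#' @slot voxelSize numeric(3), `(dx, dy, dz)` in um.
#' @seealso [channelStack()], [renderStack()], [segmentStack()]
#' @export
setClass("ChannelStack",
  representation(cw = "array", af594 = "array", fitc = "array",
                 voxelSize = "numeric")
)

setValidity("ChannelStack", function(object) {
  msg <- character()
  d <- dim(object@cw)
  if (length(d) != 3L)
    msg <- c(msg, "channels must be 3-D arrays")
  if (!identical(d, dim(object@af594)) || !identical(d, dim(object@fitc)))
    msg <- c(msg, "all three channels must share one shape")
  if (min(object@cw, object@af594, object@fitc) < 0)
    msg <- c(msg, "intensities must be >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (um)")
  if (length(msg)) msg else TRUE
})

#' DomainLabelVolume: per-voxel domain assignment
#'
#' Every voxel carries exactly one of the four integer codes of
#' [DOMAIN_CODES]: water (0), hydrogel (1), microsphere (2), coupon (3).
#' The microcap domain is the union of hydrogel and microsphere voxels.
#'
#' @slot labels integer array `(nx, ny, nz)`.
#' @slot voxelSize numeric(3) in um.
#' @seealso [assignDomains()], [groundTruth()], [domainCounts()]
#' @export
setClass("DomainLabelVolume",
  representation(labels = "array", voxelSize = "numeric")
)

setValidity("DomainLabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L || !is.integer(object@labels))
    msg <- c(msg, "labels must be a 3-D integer array")
  if (!all(object@labels %in% DOMAIN_CODES))
    msg <- c(msg, "labels must be domain codes 0 (water) .. 3 (coupon)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (um)")
  if (length(msg)) msg else TRUE
})

#' SegmentationParams: tunables of the four-domain segmentation
#'
#' @slot histogramBins integer(1), histogram bins for Otsu (default 256;
#'   intensities are min-max scaled first so bit depth does not matter).
#' @slot minRegionVoxels integer(1), connected components of the filled
#'   hydrogel mask smaller than this are discarded (default 64; the source
#'   procedure says only "very small").
#' @slot couponSearchFraction numeric(1), fraction of the stack (from the
#'   bottom) searched for the coupon edge along z (default 0.5).
#' @slot couponBiasLayers integer(1), z-layers above the detected edge also
#'   labeled coupon (default 1), deliberately favoring coupon over
#'   water/hydrogel at the interface.
#' @seealso [segmentationParams()], [segmentStack()]
#' @export
setClass("SegmentationParams",
  representation(histogramBins = "integer", minRegionVoxels = "integer",
                 couponSearchFraction = "numeric", couponBiasLayers = "integer")
)

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@histogramBins < 2L) msg <- c(msg, "histogramBins must be >= 2")
  if (object@minRegionVoxels < 0L) msg <- c(msg, "minRegionVoxels must be >= 0")
  if (object@couponSearchFraction <= 0 || object@couponSearchFraction > 1)
    msg <- c(msg, "couponSearchFraction must be in (0, 1]")
  if (object@couponBiasLayers < 0L) msg <- c(msg, "couponBiasLayers must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PartitionResult: per-domain FITC means and the partition coefficient
#'
#' The microcap partition coefficient is
#' \deqn{K_P = \frac{[\mathrm{FITC}]_{microcap}}{[\mathrm{FITC}]_{water}}}
#' with the microcap mean taken voxel-weighted over the hydrogel union
#' microsphere domains and the water mean over the water domain excluding the
#' coupon-adjacent guard layers (the surface reflection would bias it).
#'
#' @slot domainMeans named numeric, mean FITC per nonempty domain.
#' @slot domainCounts named numeric, voxel count per domain.
#' @slot fitcMicrocap numeric(1), voxel-weighted mean over hydrogel+microsphere.
#' @slot fitcWater numeric(1), mean over the (guarded) water domain.
#' @slot kp numeric(1), the partition coefficient.
#' @slot nWaterExcluded numeric(1), water voxels dropped by the guard band.
#' @seealso [partitionCoefficient()]
#' @export
setClass("PartitionResult",
  representation(domainMeans = "numeric", domainCounts = "numeric",
                 fitcMicrocap = "numeric", fitcWater = "numeric",
                 kp = "numeric", nWaterExcluded = "numeric")
)

setValidity("PartitionResult", function(object) {
  if (object@kp < 0) return("kp must be >= 0")
  if (object@fitcWater > 0 &&
      abs(object@kp - object@fitcMicrocap / object@fitcWater) > 1e-8)
    return("kp must equal fitcMicrocap / fitcWater")
  TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "MicrocapGeometry", function(object) {
  cat("MicrocapGeometry\n",
      sprintf("  cap: radius %.1f um at (%.1f, %.1f), coupon z = %.2f um\n",
              object@capRadius, object@capCenter[1L], object@capCenter[2L],
              object@couponZ),
      sprintf("  spheres: %d (CW penetration %.1f um)\n",
              nrow(object@spheres), object@cwPenetrationDepth), sep = "")
})

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@fitc)
  cat(sprintf(
    "ChannelStack: %d x %d x %d voxels (%.2f x %.2f x %.2f um), channels CW/AF594/FITC\n",
    d[1L], d[2L], d[3L], object@voxelSize[1L], object@voxelSize[2L],
    object@voxelSize[3L]))
})

setMethod("show", "DomainLabelVolume", function(object) {
  d <- dim(object@labels)
  cnt <- domainCounts(object)
  cat(sprintf("DomainLabelVolume: %d x %d x %d voxels\n", d[1L], d[2L], d[3L]))
  cat("  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "PartitionResult", function(object) {
  cat("PartitionResult\n")
  cat(sprintf("  [FITC]microcap = %.4g, [FITC]water = %.4g\n",
              object@fitcMicrocap, object@fitcWater))
  cat(sprintf("  KP = %.4f\n", object@kp))
})
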