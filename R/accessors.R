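## Constructors and accessors. Bioconductor convention: users never touch
## slots directly.

#' Construct a ConcentrationField
#'
#' @param fitcWater,fitcHydrogel,fitcMicrosphere FITC-nanodextran equilibrium
#'   intensities in water, hydrogel and microspheres (arbitrary units, >= 0).
#'   Microspheres are impermeable polystyrene, so their FITC level defaults
#'   to 0.
#' @param cwShell Calcofluor White intensity of the stained shell.
#' @param af594Sphere AF594 intensity inside microspheres.
#' @param couponReflection additive FITC intensity of the coupon surface
#'   reflection layer.
#' @return A [ConcentrationField-class] object.
#' @examples
#' concentrationField(fitcWater = 100, fitcHydrogel = 70)
#' @export
concentrationField <- function(fitcWater = 100, fitcHydrogel = 70,
                               fitcMicrosphere = 0, cwShell = 200,
                               af594Sphere = 200, couponReflection = 300) {
  new("ConcentrationField",
      fitcWater = as.numeric(fitcWater),
      fitcHydrogel = as.numeric(fitcHydrogel),
      fitcMicrosphere = as.numeric(fitcMicrosphere),
      cwShell = as.numeric(cwShell),
      af594Sphere = as.numeric(af594Sphere),
      couponReflection = as.numeric(couponReflection))
}

#' Construct an ImagingConfig
#'
#' @param dim stack shape `(nx, ny, nz)` in voxels.
#' @param voxelSize voxel edge lengths `(dx, dy, dz)` in um; a scalar is
#'   recycled (isotropic grid).
#' @param noiseModel one of [noiseNone()], [noiseGaussian()],
#'   [noisePoissonGaussian()], or an equivalent list.
#' @param blurSigma Gaussian blur sigma per axis in um (0 = off).
#' @param seed mandatory RNG seed for noise.
#' @return An [ImagingConfig-class] object.
#' @examples
#' imagingConfig(dim = c(64, 64, 64), voxelSize = 1, seed = 1L)
#' @export
imagingConfig <- function(dim, voxelSize = 1, noiseModel = noiseNone(),
                          blurSigma = 0, seed = 1L) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (length(blurSigma) == 1L) blurSigma <- rep(blurSigma, 3L)
  new("ImagingConfig", dim = as.integer(dim), voxelSize = as.numeric(voxelSize),
      noiseModel = noiseModel, blurSigma = as.numeric(blurSigma),
      seed = as.integer(seed))
}

#' Noise models for phantom rendering
#'
#' `noiseNone()` renders deterministically. `noiseGaussian(sd)` adds i.i.d.
#' Gaussian read noise. `noisePoissonGaussian(gain, sd)` is the usual camera
#' model: shot noise `gain * Poisson(I / gain)` plus Gaussian read noise.
#' Negative intensities are clamped to zero after noise.
#'
#' @param sd Gaussian standard deviation (intensity units).
#' @param gain camera gain (intensity units per photon).
#' @return A list understood by [imagingConfig()].
#' @export
noiseNone <- function() list(type = "none")

#' @rdname noiseNone
#' @export
noiseGaussian <- function(sd) list(type = "gaussian", sd = as.numeric(sd))

#' @rdname noiseNone
#' @export
noisePoissonGaussian <- function(gain = 1, sd = 0)
  list(type = "poisson_gaussian", gain = as.numeric(gain), sd = as.numeric(sd))

#' Construct a ChannelStack from three intensity arrays
#'
#' @param cw,af594,fitc 3-D numeric arrays of one shape.
#' @param voxelSize `(dx, dy, dz)` in um; scalar recycled.
#' @return A [ChannelStack-class] object.
#' @export
channelStack <- function(cw, af594, fitc, voxelSize = 1) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("ChannelStack", cw = cw, af594 = af594, fitc = fitc,
      voxelSize = as.numeric(voxelSize))
}

#' Construct a DomainLabelVolume
#'
#' @param labels 3-D integer array of [DOMAIN_CODES].
#' @param voxelSize `(dx, dy, dz)` in um; scalar recycled.
#' @return A [DomainLabelVolume-class] object.
#' @export
domainLabelVolume <- function(labels, voxelSize = 1) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  storage.mode(labels) <- "integer"
  new("DomainLabelVolume", labels = labels, voxelSize = as.numeric(voxelSize))
}

#' Construct SegmentationParams
#'
#' @param histogramBins Otsu histogram bins (default 256).
#' @param minRegionVoxels small-region discard cutoff (default 64 voxels).
#' @param couponSearchFraction bottom fraction of the stack searched for the
#'   coupon edge (default 0.5).
#' @param couponBiasLayers extra layers above the detected edge labeled coupon
#'   (default 1).
#' @return A [SegmentationParams-class] object.
#' @export
segmentationParams <- function(histogramBins = 256L, minRegionVoxels = 64L,
                               couponSearchFraction = 0.5,
                               couponBiasLayers = 1L) {
  new("SegmentationParams", histogramBins = as.integer(histogramBins),
      minRegionVoxels = as.integer(minRegionVoxels),
      couponSearchFraction = as.numeric(couponSearchFraction),
      couponBiasLayers = as.integer(couponBiasLayers))
}

## ---- generics -------------------------------------------------------------

#' Accessors for microcapKP objects
#'
#' `capRadius()`, `couponZ()` and `sphereTable()` read a
#' [MicrocapGeometry-class]; `labelArray()` the integer array of a
#' [DomainLabelVolume-class]; `channel(x, name)` one channel of a
#' [ChannelStack-class]; `voxelSize()` the physical voxel size of either;
#' `domainCounts()` the voxel tally per domain; `kpValue()` the partition
#' coefficient of a [PartitionResult-class].
#'
#' @param x the object.
#' @param name for `channel()`: one of `"cw"`, `"af594"`, `"fitc"`.
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("capRadius", function(x) standardGeneric("capRadius"))
#' @rdname accessors
#' @export
setGeneric("couponZ", function(x) standardGeneric("couponZ"))
#' @rdname accessors
#' @export
setGeneric("sphereTable", function(x) standardGeneric("sphereTable"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("domainCounts", function(x) standardGeneric("domainCounts"))
#' @rdname accessors
#' @export
setGeneric("kpValue", function(x) standardGeneric("kpValue"))

#' @rdname accessors
#' @export
setMethod("capRadius", "MicrocapGeometry", function(x) x@capRadius)
#' @rdname accessors
#' @export
setMethod("couponZ", "MicrocapGeometry", function(x) x@couponZ)
#' @rdname accessors
#' @export
setMethod("sphereTable", "MicrocapGeometry", function(x) {
  sp <- x@spheres
  colnames(sp) <- c("x", "y", "z", "r")
  sp
})
#' @rdname accessors
#' @export
setMethod("labelArray", "DomainLabelVolume", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("channel", "ChannelStack", function(x, name) {
  switch(match.arg(name, c("cw", "af594", "fitc")),
         cw = x@cw, af594 = x@af594, fitc = x@fitc)
})
#' @rdname accessors
#' @export
setMethod("voxelSize", "ChannelStack", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "DomainLabelVolume", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "ImagingConfig", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("domainCounts", "DomainLabelVolume", function(x) {
  cnt <- tabulate(x@labels + 1L, nbins = 4L)
  stats::setNames(cnt, names(DOMAIN_CODES))
})
#' @rdname accessors
#' @export
setMethod("kpValue", "PartitionResult", function(x) x@kp)

#' @rdname accessors
#' @export
setGeneric("domainMeansOf", function(x) standardGeneric("domainMeansOf"))
#' @rdname accessors
#' @export
setMethod("domainMeansOf", "PartitionResult", function(x) x@domainMeans)
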