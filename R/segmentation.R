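## Four-domain segmentation of a three-channel microcap z-stack:
## microspheres by Otsu on AF594, hydrogel by Otsu on CW + per-slice region
## filling + small-region discard, coupon by a z-direction edge detector
## biased toward the coupon, remainder water.

#' Otsu threshold of an intensity collection
#'
#' Histogram-based Otsu: intensities are min-max scaled, binned into
#' `bins` equal-width bins, and the internal bin edge maximizing the
#' between-class variance of the two resulting classes is returned (on the
#' original intensity scale). Ties break toward the lowest qualifying edge.
#' Fixing the bin count (rather than the bit depth) makes the threshold
#' invariant under affine rescaling of the input.
#'
#' @param x numeric vector or array of intensities with at least two distinct
#'   values.
#' @param bins histogram bin count (default 256).
#' @return The threshold (a bin edge, original scale). Foreground is
#'   conventionally `x > threshold`.
#' @examples
#' otsuThreshold(c(rep(10, 500), rep(200, 500)))
#' @export
otsuThreshold <- function(x, bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (!length(x) || lo == hi)
    stop("degenerate histogram: input has fewer than two distinct values")
  bins <- as.integer(bins)
  idx <- pmin(floor((x - lo) / (hi - lo) * bins) + 1L, bins)
  h <- tabulate(idx, nbins = bins)
  p <- h / sum(h)
  mids <- (seq_len(bins) - 0.5) / bins
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[bins]
  k <- seq_len(bins - 1L)
  denom <- omega[k] * (1 - omega[k])
  sigma2 <- (muT * omega[k] - mu[k])^2 / denom
  sigma2[denom <= 0] <- -Inf
  kstar <- which.max(sigma2)              # first max = lowest qualifying edge
  lo + (hi - lo) * kstar / bins
}

# label connected components (26-connectivity) of a logical volume
labelComponents <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  cc_label_3d(as.logical(mask), as.integer(dim(mask)))
}

# drop connected components below a voxel-count cutoff
dropSmallRegions <- function(mask, minVoxels) {
  if (minVoxels <= 0L || !any(mask)) return(mask)
  lab <- labelComponents(mask)
  n <- attr(lab, "n_components")
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes >= minVoxels)
  out <- array(lab %in% keep, dim = dim(mask))
  out
}

#' Segment microspheres from the AF594 channel
#'
#' Voxels above the Otsu threshold of the AF594 channel. A stack may
#' legitimately contain no spheres: a degenerate (constant) channel yields an
#' empty mask with a warning rather than an error.
#'
#' Because microspheres fill at most a few percent of any stack (placement is
#' capped at a 10 percent cap-volume fraction), an Otsu mask covering more
#' than `maxForegroundFraction` of the volume can only be thresholded noise
#' on a sphere-free channel; it is replaced by an empty mask with a warning.
#'
#' @param stack a [ChannelStack-class].
#' @param params a [SegmentationParams-class].
#' @param maxForegroundFraction sparsity gate (default 0.1).
#' @return Logical array: `TRUE` = microsphere.
#' @export
segmentMicrospheres <- function(stack, params = segmentationParams(),
                                maxForegroundFraction = 0.1) {
  af <- channel(stack, "af594")
  if (min(af) == max(af)) {
    warning("AF594 channel is degenerate; returning an empty microsphere mask")
    return(array(FALSE, dim = dim(af)))
  }
  mask <- af > otsuThreshold(af, params@histogramBins)
  if (mean(mask) > maxForegroundFraction) {
    warning("AF594 channel shows no sparse microsphere signal ",
            "(thresholded fraction ", signif(mean(mask), 2),
            "); returning an empty microsphere mask")
    mask <- array(FALSE, dim = dim(af))
  }
  mask
}

#' Segment the hydrogel from the Calcofluor White channel
#'
#' The CW stain only penetrates ~10 um into the hydrogel, so a raw Otsu mask
#' is a shell around an unstained core. The shell is therefore (a) Otsu
#' thresholded, (b) region-filled per z-slice in 2-D with 4-connectivity
#' (a hemisphere's open top would defeat naive 3-D filling) and unioned
#' across slices, and (c) cleaned by discarding connected components smaller
#' than `minRegionVoxels`.
#'
#' @inheritParams segmentMicrospheres
#' @return Logical array: `TRUE` = hydrogel.
#' @export
segmentHydrogel <- function(stack, params = segmentationParams()) {
  cw <- channel(stack, "cw")
  if (min(cw) == max(cw))
    stop("no hydrogel detected: CW channel is degenerate")
  shell <- cw > otsuThreshold(cw, params@histogramBins)
  filled <- fill_holes_slices(shell, as.integer(dim(shell)))
  dropSmallRegions(filled, params@minRegionVoxels)
}

#' Segment the coupon by z-direction edge detection on the FITC channel
#'
#' The polycarbonate coupon reflects green light at its surface, producing a
#' bright FITC layer above the dark coupon interior. For every (x, y) column
#' the detector locates the maximum positive-to-negative intensity transition
#' along z (the drop from the reflection layer into the water/hydrogel above)
#' within the bottom `couponSearchFraction` of the stack. That layer, all
#' layers below it, and `couponBiasLayers` above it are labeled coupon —
#' deliberately favoring coupon over water or hydrogel, since the accuracy of
#' those domains matters more. Columns with no detectable edge (no positive
#' drop) fall back to the modal detected plane.
#'
#' @inheritParams segmentMicrospheres
#' @return Logical array: `TRUE` = coupon, with attribute `planes`, the
#'   per-column detected edge layer (nx x ny integer matrix).
#' @export
segmentCoupon <- function(stack, params = segmentationParams()) {
  fitc <- channel(stack, "fitc")
  d <- dim(fitc)
  nz <- d[3L]
  K <- max(2L, as.integer(floor(nz * params@couponSearchFraction)))
  M <- matrix(fitc, nrow = d[1L] * d[2L], ncol = nz)
  D <- M[, seq_len(K - 1L), drop = FALSE] - M[, 2L:K, drop = FALSE]
  kstar <- max.col(D, ties.method = "first")
  drop <- D[cbind(seq_len(nrow(D)), kstar)]
  detectable <- drop > 0
  if (!any(detectable))
    stop("coupon not found: no column shows a falling FITC edge along z")
  modal <- as.integer(names(which.max(table(kstar[detectable]))))
  planes <- ifelse(detectable, kstar, modal)
  top <- pmin(planes + params@couponBiasLayers, nz)
  mask <- outer(top, seq_len(nz), ">=")
  mask <- array(mask, dim = d)
  attr(mask, "planes") <- matrix(as.integer(planes), d[1L], d[2L])
  mask
}

#' Combine the three masks into a domain label volume
#'
#' Precedence where masks overlap: coupon > microsphere > hydrogel; voxels in
#' no mask are water. The output is a partition — every voxel carries exactly
#' one code.
#'
#' @param sphereMask,hydrogelMask,couponMask logical arrays of one shape.
#' @param voxelSize `(dx, dy, dz)` in um; scalar recycled.
#' @return A [DomainLabelVolume-class].
#' @export
assignDomains <- function(sphereMask, hydrogelMask, couponMask, voxelSize = 1) {
  d <- dim(hydrogelMask)
  if (!identical(d, dim(sphereMask)) || !identical(d, dim(couponMask)))
    stop("masks must share one shape")
  lab <- array(DOMAIN_CODES[["water"]], dim = d)
  lab[hydrogelMask] <- DOMAIN_CODES[["hydrogel"]]
  lab[sphereMask] <- DOMAIN_CODES[["microsphere"]]
  lab[couponMask] <- DOMAIN_CODES[["coupon"]]
  domainLabelVolume(lab, voxelSize)
}

#' Segment a full stack into the four domains
#'
#' Runs [segmentMicrospheres()], [segmentHydrogel()] and [segmentCoupon()] and
#' combines them with [assignDomains()].
#'
#' @inheritParams segmentMicrospheres
#' @return A [DomainLabelVolume-class].
#' @examples
#' g <- makeGeometry(capRadius = 20, couponZ = 2, seed = 1)
#' cfg <- imagingConfig(dim = c(48, 48, 32), voxelSize = 1, seed = 1)
#' stk <- renderStack(g, concentrationField(), cfg)
#' seg <- segmentStack(stk)
#' domainCounts(seg)
#' @export
segmentStack <- function(stack, params = segmentationParams()) {
  sph <- segmentMicrospheres(stack, params)
  hyd <- segmentHydrogel(stack, params)
  cou <- segmentCoupon(stack, params)
  assignDomains(sph, hyd, cou, voxelSize(stack))
}
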