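## Synthetic microcap phantoms: geometry sampling, analytic ground truth,
## and rendering of noisy three-channel z-stacks with a known true KP.

# run expr with a fixed RNG state, restoring the caller's state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic microcap geometry
#'
#' Builds a hemispherical hydrogel cap resting on the coupon plane and places
#' `nSpheres` non-overlapping microspheres uniformly inside it by rejection
#' sampling. Imaged caps are below 250 um diameter and microspheres are
#' 0.7-0.9 um diameter polystyrene, hence the defaults.
#'
#' @param capRadius cap radius in um (default 100; keep `2 * capRadius <= 250`
#'   for study-like scenarios).
#' @param couponZ coupon surface height in um (coupon fills all z below it).
#' @param nSpheres number of microspheres to place.
#' @param sphereRadiusRange radii are drawn uniformly from this range (um);
#'   default `c(0.35, 0.45)`, i.e. 0.7-0.9 um diameters.
#' @param cwPenetrationDepth stained-shell thickness in um (default 10).
#' @param capCenter (x, y) of the cap center; defaults to the origin-offset
#'   `(capRadius + 2, capRadius + 2)` so the cap sits clear of the frame edge.
#' @param seed RNG seed; identical seeds give identical geometries.
#' @param maxAttempts rejection-sampling budget per sphere.
#' @return A [MicrocapGeometry-class] object.
#' @details Requested sphere volume above 10 percent of the cap volume is
#'   refused up front (rejection sampling would not reliably terminate);
#'   exceeding `maxAttempts` raises an "overpacked geometry" error.
#' @examples
#' makeGeometry(capRadius = 50, nSpheres = 10, seed = 1)
#' @export
makeGeometry <- function(capRadius = 100, couponZ = 2, nSpheres = 0L,
                         sphereRadiusRange = c(0.35, 0.45),
                         cwPenetrationDepth = 10, capCenter = NULL,
                         seed = 1L, maxAttempts = 1000L) {
  if (capRadius <= 0 || couponZ < 0 || cwPenetrationDepth <= 0 ||
      any(sphereRadiusRange <= 0))
    stop("negative or zero dimensions are not a valid geometry")
  if (capRadius <= max(sphereRadiusRange))
    stop("capRadius must exceed the largest sphere radius")
  if (is.null(capCenter)) capCenter <- rep(capRadius + 2, 2L)
  nSpheres <- as.integer(nSpheres)
  if (nSpheres < 0L) stop("nSpheres must be >= 0")

  capVol <- (2 / 3) * pi * capRadius^3
  reqVol <- nSpheres * (4 / 3) * pi * mean(sphereRadiusRange)^3
  if (reqVol > 0.1 * capVol)
    stop("overpacked geometry: requested sphere volume fraction exceeds 10%")

  spheres <- matrix(numeric(0), ncol = 4L)
  if (nSpheres > 0L) {
    spheres <- withSeed(seed, {
      placed <- matrix(NA_real_, nrow = nSpheres, ncol = 4L)
      for (i in seq_len(nSpheres)) {
        r <- runif(1L, sphereRadiusRange[1L], sphereRadiusRange[2L])
        ok <- FALSE
        for (a in seq_len(maxAttempts)) {
          # uniform in the ball of radius capRadius - r, upper half only
          u <- runif(3L, -1, 1)
          if (sum(u^2) > 1) next
          p <- u * (capRadius - r)
          z <- abs(p[3L])                      # fold into the hemisphere
          if (z < r) next                      # must clear the coupon plane
          cand <- c(capCenter[1L] + p[1L], capCenter[2L] + p[2L],
                    couponZ + z, r)
          if (i > 1L) {
            prev <- placed[seq_len(i - 1L), , drop = FALSE]
            d2 <- (prev[, 1L] - cand[1L])^2 + (prev[, 2L] - cand[2L])^2 +
                  (prev[, 3L] - cand[3L])^2
            if (any(d2 < (prev[, 4L] + r)^2)) next
          }
          placed[i, ] <- cand
          ok <- TRUE
          break
        }
        if (!ok) stop("overpacked geometry: sphere placement failed after ",
                      maxAttempts, " attempts")
      }
      placed
    })
  }
  new("MicrocapGeometry", capCenter = as.numeric(capCenter),
      capRadius = as.numeric(capRadius), couponZ = as.numeric(couponZ),
      spheres = spheres, cwPenetrationDepth = as.numeric(cwPenetrationDepth))
}

#' Approximate microsphere count for a weight percentage
#'
#' The study loads hydrogels with 0.01 wt percent microspheres. This helper
#' converts a weight percentage to an approximate sphere count for a given cap,
#' assuming the cap interior has the density of water. It is a documented
#' approximation: real loading is set at the solution-mixing stage, not per
#' cap.
#'
#' @param weightPercent sphere mass as a percentage of cap mass (default 0.01).
#' @param capRadius cap radius in um.
#' @param sphereRadius representative sphere radius in um (default 0.4).
#' @param sphereDensity polystyrene density in g/cm^3 (default 1.05).
#' @param gelDensity hydrated-gel density in g/cm^3 (default 1.00).
#' @return Integer sphere count (rounded).
#' @export
sphereCountForWeightPercent <- function(weightPercent = 0.01, capRadius,
                                        sphereRadius = 0.4,
                                        sphereDensity = 1.05,
                                        gelDensity = 1.00) {
  capVol <- (2 / 3) * pi * capRadius^3
  sphVol <- (4 / 3) * pi * sphereRadius^3
  as.integer(round((weightPercent / 100) * capVol * gelDensity /
                   (sphVol * sphereDensity)))
}

# voxel-center coordinates along each axis (um); centers at (i - 1/2) * d
voxelCenters <- function(config) {
  d <- config@dim; v <- config@voxelSize
  list(x = (seq_len(d[1L]) - 0.5) * v[1L],
       y = (seq_len(d[2L]) - 0.5) * v[2L],
       z = (seq_len(d[3L]) - 0.5) * v[3L])
}

# check the stack physically contains cap + coupon margin
checkFits <- function(geometry, config) {
  ext <- config@dim * config@voxelSize
  cc <- geometry@capCenter; R <- geometry@capRadius
  if (cc[1L] - R < 0 || cc[2L] - R < 0 ||
      cc[1L] + R > ext[1L] || cc[2L] + R > ext[2L] ||
      geometry@couponZ + R > ext[3L])
    stop("stack too small: geometry does not fit in ",
         paste(round(ext, 2), collapse = " x "), " um")
  invisible(TRUE)
}

# labels + squared distance from cap center, shared by groundTruth/renderStack
phantomLabels <- function(geometry, config) {
  checkFits(geometry, config)
  ctr <- voxelCenters(config)
  d <- config@dim
  cc <- geometry@capCenter; R <- geometry@capRadius; cz <- geometry@couponZ
  dx2 <- (ctr$x - cc[1L])^2
  dy2 <- (ctr$y - cc[2L])^2
  dz2 <- (ctr$z - cz)^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")        # (nx, ny, nz)
  couponLayer <- ctr$z <= cz
  labels <- array(DOMAIN_CODES[["water"]], dim = d)
  inCap <- r2 <= R^2
  if (any(couponLayer)) inCap[, , couponLayer] <- FALSE
  labels[inCap] <- DOMAIN_CODES[["hydrogel"]]
  sp <- geometry@spheres
  if (nrow(sp) > 0L) {
    v <- config@voxelSize
    for (i in seq_len(nrow(sp))) {
      ix <- which(abs(ctr$x - sp[i, 1L]) <= sp[i, 4L] + v[1L])
      iy <- which(abs(ctr$y - sp[i, 2L]) <= sp[i, 4L] + v[2L])
      iz <- which(abs(ctr$z - sp[i, 3L]) <= sp[i, 4L] + v[3L])
      if (!length(ix) || !length(iy) || !length(iz)) next
      sub <- outer(outer((ctr$x[ix] - sp[i, 1L])^2,
                         (ctr$y[iy] - sp[i, 2L])^2, "+"),
                   (ctr$z[iz] - sp[i, 3L])^2, "+") <= sp[i, 4L]^2
      idx <- which(sub, arr.ind = TRUE)
      if (nrow(idx)) {
        lin <- cbind(ix[idx[, 1L]], iy[idx[, 2L]], iz[idx[, 3L]])
        labels[lin] <- DOMAIN_CODES[["microsphere"]]
      }
    }
  }
  if (any(couponLayer))
    labels[, , couponLayer] <- DOMAIN_CODES[["coupon"]]
  storage.mode(labels) <- "integer"
  list(labels = labels, r2 = r2, couponLayer = couponLayer)
}

#' Analytic ground truth for a phantom
#'
#' Assigns every voxel to exactly one domain by testing its center against the
#' analytic geometry (no partial-volume weighting), and, when a concentration
#' field is supplied, computes the true partition coefficient: the
#' voxel-count-weighted mean FITC level over the microcap domain (hydrogel
#' union microsphere) divided by the water level.
#'
#' @param geometry a [MicrocapGeometry-class].
#' @param config an [ImagingConfig-class]; the stack must contain the
#'   geometry.
#' @param field optionally a [ConcentrationField-class]; needed for `trueKp`.
#' @return A list with `labels` (a [DomainLabelVolume-class]) and `trueKp`
#'   (`NA` when no field is given).
#' @examples
#' g <- makeGeometry(capRadius = 20, couponZ = 2, seed = 1)
#' cfg <- imagingConfig(dim = c(48, 48, 32), voxelSize = 1, seed = 1)
#' gt <- groundTruth(g, cfg, concentrationField(fitcWater = 100, fitcHydrogel = 70))
#' gt$trueKp
#' @export
groundTruth <- function(geometry, config, field = NULL) {
  ph <- phantomLabels(geometry, config)
  kp <- NA_real_
  if (!is.null(field)) {
    if (field@fitcWater <= 0)
      stop("undefined partition coefficient: fitcWater must be > 0")
    nh <- sum(ph$labels == DOMAIN_CODES[["hydrogel"]])
    ns <- sum(ph$labels == DOMAIN_CODES[["microsphere"]])
    if (nh + ns == 0L)
      stop("undefined partition coefficient: microcap domain is empty")
    kp <- (nh * field@fitcHydrogel + ns * field@fitcMicrosphere) /
          ((nh + ns) * field@fitcWater)
  }
  list(labels = domainLabelVolume(ph$labels, config@voxelSize), trueKp = kp)
}

# separable Gaussian blur; sigma in voxels per axis, truncated at 3 sigma,
# kernels renormalized at the edges
gaussianBlur3d <- function(a, sigmaVox) {
  blurAxis <- function(a, axis, s) {
    if (s <= 0) return(a)
    rad <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-rad, rad), sd = s)
    n <- dim(a)[axis]
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      idx <- (j - rad):(j + rad)
      keep <- idx >= 1L & idx <= n
      K[j, idx[keep]] <- k[keep] / sum(k[keep])
    }
    perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
    b <- aperm(a, perm)
    db <- dim(b)
    b <- K %*% matrix(b, nrow = db[1L])
    dim(b) <- db
    aperm(b, order(perm))
  }
  for (ax in 1:3) a <- blurAxis(a, ax, sigmaVox[ax])
  a
}

applyNoise <- function(a, model) {
  switch(model$type,
    none = a,
    gaussian = pmax(a + rnorm(length(a), 0, model$sd), 0),
    poisson_gaussian = {
      gain <- model$gain
      shot <- gain * rpois(length(a), as.vector(a) / gain)
      out <- shot + rnorm(length(a), 0, model$sd)
      array(pmax(out, 0), dim = dim(a))
    },
    stop("unknown noise model: ", model$type))
}

#' Render a phantom into a three-channel z-stack
#'
#' Renders piecewise-constant channels from the analytic geometry, then
#' applies optional Gaussian blur and the configured camera noise (noise last).
#' The CW channel is nonzero only in the stained hydrogel shell — hydrogel
#' voxels within `cwPenetrationDepth` of the cap's outer spherical surface.
#' The AF594 channel is nonzero only inside microspheres. The FITC channel
#' carries the domain concentration everywhere (zero inside the coupon) plus
#' the coupon reflection added across the single topmost coupon z-layer.
#'
#' @inheritParams groundTruth
#' @param field a [ConcentrationField-class].
#' @return A [ChannelStack-class]. Identical `(geometry, field, config)` —
#'   including `config@seed` — give bit-identical stacks.
#' @examples
#' g <- makeGeometry(capRadius = 20, couponZ = 2, seed = 1)
#' cfg <- imagingConfig(dim = c(48, 48, 32), voxelSize = 1, seed = 7)
#' stk <- renderStack(g, concentrationField(), cfg)
#' @export
renderStack <- function(geometry, field, config) {
  ph <- phantomLabels(geometry, config)
  lab <- ph$labels
  lut <- c(field@fitcWater, field@fitcHydrogel, field@fitcMicrosphere, 0)
  fitc <- array(lut[lab + 1L], dim = dim(lab))
  if (any(ph$couponLayer)) {
    top <- max(which(ph$couponLayer))
    fitc[, , top] <- fitc[, , top] + field@couponReflection
  }
  shell <- lab == DOMAIN_CODES[["hydrogel"]] &
           ph$r2 >= (geometry@capRadius - geometry@cwPenetrationDepth)^2
  cw <- array(0, dim = dim(lab)); cw[shell] <- field@cwShell
  af <- array(0, dim = dim(lab))
  af[lab == DOMAIN_CODES[["microsphere"]]] <- field@af594Sphere
  if (any(config@blurSigma > 0)) {
    sv <- config@blurSigma / config@voxelSize
    cw <- gaussianBlur3d(cw, sv)
    af <- gaussianBlur3d(af, sv)
    fitc <- gaussianBlur3d(fitc, sv)
  }
  if (config@noiseModel$type != "none") {
    chans <- withSeed(config@seed, {
      list(cw = applyNoise(cw, config@noiseModel),
           af = applyNoise(af, config@noiseModel),
           fitc = applyNoise(fitc, config@noiseModel))
    })
    cw <- chans$cw; af <- chans$af; fitc <- chans$fitc
  }
  channelStack(cw, af, fitc, config@voxelSize)
}
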