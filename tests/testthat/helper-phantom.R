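# Shared fixture builders: everything is generated in code at test time.

# a cap that comfortably fits a 64^3 stack on a 1 um grid
smallScene <- function(kp = 0.7, capRadius = 24, dimVox = 64L, nSpheres = 0L,
                       noise = noiseNone(), seed = 1L, fitcWater = 100) {
  geom <- makeGeometry(capRadius = capRadius, couponZ = 2,
                       nSpheres = nSpheres, seed = seed)
  cfg <- imagingConfig(dim = rep(dimVox, 3L), voxelSize = 1,
                       noiseModel = noise, seed = seed)
  fld <- concentrationField(fitcWater = fitcWater,
                            fitcHydrogel = kp * fitcWater,
                            fitcMicrosphere = kp * fitcWater,
                            cwShell = 2 * fitcWater,
                            af594Sphere = 2 * fitcWater,
                            couponReflection = 3 * fitcWater)
  list(geom = geom, cfg = cfg, fld = fld)
}

# fine-grid scene that resolves 0.7-0.9 um microspheres (0.2 um voxels)
sphereScene <- function(nSpheres = 20L, seed = 1L, noiseSd = 0) {
  geom <- makeGeometry(capRadius = 5, couponZ = 0.4, nSpheres = nSpheres,
                       seed = seed)
  noise <- if (noiseSd > 0) noiseGaussian(noiseSd) else noiseNone()
  cfg <- imagingConfig(dim = c(64L, 64L, 40L), voxelSize = 0.2,
                       noiseModel = noise, seed = seed)
  fld <- concentrationField(fitcWater = 100, fitcHydrogel = 70,
                            cwShell = 200, af594Sphere = 200,
                            couponReflection = 300)
  list(geom = geom, cfg = cfg, fld = fld)
}

# independent brute-force Otsu: naive loop over every candidate bin edge,
# recomputing class weights and means by direct summation
bruteForceOtsu <- function(x, bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  idx <- pmin(floor((x - lo) / (hi - lo) * bins) + 1L, bins)
  h <- tabulate(idx, nbins = bins)
  mids <- (seq_len(bins) - 0.5) / bins
  best <- -Inf; bestK <- NA_integer_
  for (k in seq_len(bins - 1L)) {
    n0 <- sum(h[1:k]); n1 <- sum(h[(k + 1L):bins])
    if (n0 == 0L || n1 == 0L) next
    mu0 <- sum(h[1:k] * mids[1:k]) / n0
    mu1 <- sum(h[(k + 1L):bins] * mids[(k + 1L):bins]) / n1
    v <- (n0 / length(x)) * (n1 / length(x)) * (mu0 - mu1)^2
    if (v > best + 1e-15) { best <- v; bestK <- k }
  }
  lo + (hi - lo) * bestK / bins
}
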