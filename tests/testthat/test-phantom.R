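test_that("makeGeometry honors sphere size, containment and packing invariants", {
  # no spheres: trivial geometry
  g0 <- makeGeometry(capRadius = 100, nSpheres = 0, seed = 1)
  expect_equal(nrow(sphereTable(g0)), 0L)
  expect_equal(capRadius(g0), 100)

  # a 250 um diameter cap: all sampled diameters within 0.7-0.9 um
  g1 <- makeGeometry(capRadius = 125, nSpheres = 40, seed = 2)
  d <- 2 * sphereTable(g1)[, "r"]
  expect_true(all(d >= 0.7 & d <= 0.9))

  # exhaustive pairwise oracle: 50 spheres in a 50 um cap, all 1225 pairs
  g2 <- makeGeometry(capRadius = 50, nSpheres = 50, seed = 3)
  sp <- sphereTable(g2)
  expect_equal(nrow(sp), 50L)
  for (i in 1:49) for (j in (i + 1):50) {
    dij <- sqrt(sum((sp[i, 1:3] - sp[j, 1:3])^2))
    expect_gte(dij, sp[i, "r"] + sp[j, "r"] - 1e-9)
  }
  # every sphere surface point inside the hemisphere and above the coupon
  ctr <- c(g2@capCenter, couponZ(g2))
  for (i in 1:50) {
    expect_lte(sqrt(sum((sp[i, 1:3] - ctr)^2)) + sp[i, "r"],
               capRadius(g2) + 1e-9)
    expect_gte(sp[i, "z"] - sp[i, "r"], couponZ(g2) - 1e-9)
  }
})

test_that("makeGeometry is deterministic in the seed and rejects bad requests", {
  a <- makeGeometry(capRadius = 30, nSpheres = 25, seed = 7)
  b <- makeGeometry(capRadius = 30, nSpheres = 25, seed = 7)
  expect_identical(sphereTable(a), sphereTable(b))
  c <- makeGeometry(capRadius = 30, nSpheres = 25, seed = 8)
  expect_false(identical(sphereTable(a), sphereTable(c)))

  expect_error(makeGeometry(capRadius = -5), "negative")
  expect_error(makeGeometry(capRadius = 2, nSpheres = 4000, seed = 1),
               "overpacked")
})

test_that("sphereCountForWeightPercent scales with cap volume", {
  n1 <- sphereCountForWeightPercent(0.01, capRadius = 100)
  n2 <- sphereCountForWeightPercent(0.01, capRadius = 200)
  expect_equal(n2 / n1, 8, tolerance = 0.01)   # volume scales as R^3
  expect_gt(n1, 0)
})

test_that("groundTruth labels partition the stack and match analytic volumes", {
  sc <- smallScene(kp = 0.6)
  gt <- groundTruth(sc$geom, sc$cfg, sc$fld)
  cnt <- domainCounts(gt$labels)
  expect_equal(sum(cnt), prod(sc$cfg@dim))          # label partition
  expect_equal(cnt[["microsphere"]], 0L)            # no spheres requested

  # homogeneous field: true KP is exactly 1
  hom <- concentrationField(fitcWater = 55, fitcHydrogel = 55,
                            fitcMicrosphere = 55)
  expect_equal(groundTruth(sc$geom, sc$cfg, hom)$trueKp, 1.0)

  expect_error(
    groundTruth(sc$geom, sc$cfg, concentrationField(fitcWater = 0)),
    "undefined partition coefficient")
})

test_that("voxelized hemisphere volume agrees with analytic and refined-grid oracles", {
  # 50 um hemisphere on a 1 um grid: within 2% of (2/3) pi R^3
  geom <- makeGeometry(capRadius = 50, couponZ = 2, seed = 1)
  cfg <- imagingConfig(dim = c(104L, 104L, 56L), voxelSize = 1, seed = 1)
  gt <- groundTruth(geom, cfg)
  cnt <- domainCounts(gt$labels)
  vox <- cnt[["hydrogel"]] + cnt[["microsphere"]]
  expect_equal(vox, (2 / 3) * pi * 50^3, tolerance = 0.02)

  # tolerance verified against a 10x finer brute-force count (20 um cap):
  # count voxel centers inside the hemisphere slice by slice at 0.1 um
  geom2 <- makeGeometry(capRadius = 20, couponZ = 2, seed = 1)
  cfg2 <- imagingConfig(dim = c(44L, 44L, 26L), voxelSize = 1, seed = 1)
  coarse <- sum(labelArray(groundTruth(geom2, cfg2)$labels) %in% 1:2)
  f <- 0.1
  zc <- seq(f / 2, 20, by = f)
  xy <- seq(-20 + f / 2, 20, by = f)
  fine <- sum(vapply(zc, function(z) {
    r2 <- 20^2 - z^2
    if (r2 <= 0) return(0)
    sum(outer(xy^2, xy^2, "+") <= r2)
  }, numeric(1)))
  expect_equal(coarse, fine * f^3, tolerance = 0.02)
})

test_that("renderStack is piecewise-constant, shell-limited and deterministic", {
  sc <- smallScene(kp = 0.6, nSpheres = 30)
  gt <- groundTruth(sc$geom, sc$cfg, sc$fld)
  lab <- labelArray(gt$labels)
  stk <- renderStack(sc$geom, sc$fld, sc$cfg)

  # dark frame: all-zero concentrations render to an all-zero stack
  dark <- concentrationField(0, 0, 0, 0, 0, 0)
  stkd <- renderStack(sc$geom, dark, sc$cfg)
  expect_equal(max(channel(stkd, "cw"), channel(stkd, "af594"),
                   channel(stkd, "fitc")), 0)

  # piecewise-constant rendering oracle (reflection layer is coupon-labeled,
  # so water voxels are untouched by it)
  fitc <- channel(stk, "fitc")
  expect_equal(unique(as.vector(fitc[lab == 0L])), sc$fld@fitcWater)
  expect_equal(unique(as.vector(fitc[lab == 1L])), sc$fld@fitcHydrogel)

  # CW support inside hydrogel, within penetration depth of the outer surface
  cw <- channel(stk, "cw")
  expect_true(all(lab[cw > 0] == 1L))
  ctr <- list(x = seq_len(64) - 0.5, y = seq_len(64) - 0.5,
              z = seq_len(64) - 0.5)
  pos <- which(cw > 0, arr.ind = TRUE)
  r <- sqrt((ctr$x[pos[, 1]] - sc$geom@capCenter[1])^2 +
            (ctr$y[pos[, 2]] - sc$geom@capCenter[2])^2 +
            (ctr$z[pos[, 3]] - couponZ(sc$geom))^2)
  diagv <- sqrt(3)                               # 1 um isotropic grid
  expect_true(all(capRadius(sc$geom) - r <= 10 + diagv))

  # AF594 support equals the microsphere domain (noise-free)
  af <- channel(stk, "af594")
  expect_true(all(lab[af > 0] == 2L))
  expect_true(all(af[lab == 2L] > 0))

  # bit-for-bit determinism under noise with one seed
  cfgN <- imagingConfig(dim = rep(64L, 3), voxelSize = 1,
                        noiseModel = noisePoissonGaussian(1, 5), seed = 11)
  s1 <- renderStack(sc$geom, sc$fld, cfgN)
  s2 <- renderStack(sc$geom, sc$fld, cfgN)
  expect_identical(channel(s1, "fitc"), channel(s2, "fitc"))
  expect_identical(channel(s1, "cw"), channel(s2, "cw"))

  # stack too small for the geometry
  tiny <- imagingConfig(dim = c(16L, 16L, 16L), voxelSize = 1, seed = 1)
  expect_error(renderStack(sc$geom, sc$fld, tiny), "too small")
})

test_that("true KP is invariant under uniform FITC rescaling", {
  sc <- smallScene(kp = 0.37)
  k1 <- groundTruth(sc$geom, sc$cfg, sc$fld)$trueKp
  scaled <- concentrationField(fitcWater = 7.7 * sc$fld@fitcWater,
                               fitcHydrogel = 7.7 * sc$fld@fitcHydrogel,
                               fitcMicrosphere = 7.7 * sc$fld@fitcMicrosphere)
  k2 <- groundTruth(sc$geom, sc$cfg, scaled)$trueKp
  expect_equal(k1, k2)
  expect_equal(k1, 0.37)
})
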