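test_that("otsuThreshold separates a two-level image and matches the brute-force maximizer", {
  x <- c(rep(10, 500), rep(200, 500))
  th <- otsuThreshold(x)
  expect_gt(th, 10)
  expect_lt(th, 200)
  expect_true(sum(x > th) > 0 && sum(x <= th) > 0)

  # oracle equivalence on fuzzed mixtures, including skewed and overlapping
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    x <- c(rnorm(n1, runif(1, 0, 50), runif(1, 1, 20)),
           rnorm(n2, runif(1, 60, 200), runif(1, 1, 40)))
    expect_equal(otsuThreshold(x), bruteForceOtsu(x))
  }
  # uniform noise (no real classes): still the brute-force maximizer
  for (i in 1:5) {
    x <- runif(sample(100:1000, 1), 0, 100)
    expect_equal(otsuThreshold(x), bruteForceOtsu(x))
  }
  expect_error(otsuThreshold(rep(3, 10)), "degenerate histogram")
})

test_that("Otsu-based masks are invariant under affine intensity rescaling", {
  set.seed(7)
  x <- c(rnorm(400, 20, 5), rnorm(300, 120, 15))
  m1 <- x > otsuThreshold(x)
  y <- 3.7 * x + 112
  m2 <- y > otsuThreshold(y)
  expect_identical(m1, m2)
})

test_that("segmentMicrospheres recovers sphere masks, counts and volumes", {
  # no spheres, dark AF594: empty mask with a warning
  sc0 <- smallScene(nSpheres = 0)
  stk0 <- renderStack(sc0$geom, sc0$fld, sc0$cfg)
  expect_warning(m0 <- segmentMicrospheres(stk0), "degenerate")
  expect_false(any(m0))

  # noise-free fine grid: mask equals ground truth on >= 99.9% of voxels
  sc <- sphereScene(nSpheres = 20, seed = 5)
  gt <- groundTruth(sc$geom, sc$cfg)
  truth <- labelArray(gt$labels) == 2L
  stk <- renderStack(sc$geom, sc$fld, sc$cfg)
  m <- segmentMicrospheres(stk)
  expect_gte(mean(m == truth), 0.999)

  # moderate noise (5% of sphere signal): 20 connected components recovered
  scn <- sphereScene(nSpheres = 20, seed = 5, noiseSd = 0.05 * 200)
  stkn <- renderStack(scn$geom, scn$fld, scn$cfg)
  mn <- segmentMicrospheres(stkn)
  lab <- microcapKP:::labelComponents(mn)
  expect_equal(attr(lab, "n_components"), 20L)

  # recovered volume within 20% of the analytic total on the 0.2 um grid
  sp <- sphereTable(sc$geom)
  analytic <- sum((4 / 3) * pi * sp[, "r"]^3)
  expect_equal(sum(m) * 0.2^3, analytic, tolerance = 0.2)
})

test_that("segmentHydrogel fills the unstained core and ignores small junk", {
  # penetration >= radius: the whole cap is stained, filling is a no-op
  geom <- makeGeometry(capRadius = 15, couponZ = 2, cwPenetrationDepth = 20,
                       seed = 1)
  cfg <- imagingConfig(dim = c(40L, 40L, 24L), voxelSize = 1, seed = 1)
  fld <- concentrationField()
  stk <- renderStack(geom, fld, cfg)
  m <- segmentHydrogel(stk, segmentationParams(minRegionVoxels = 0L))
  truth <- labelArray(groundTruth(geom, cfg)$labels) == 1L
  expect_identical(array(m, dim = dim(truth)), truth)

  # 10 um shell on a 100 um cap: post-fill mask covers >= 95% of the hydrogel
  geom2 <- makeGeometry(capRadius = 50, couponZ = 2, seed = 1)
  cfg2 <- imagingConfig(dim = c(104L, 104L, 56L), voxelSize = 1, seed = 1)
  stk2 <- renderStack(geom2, fld, cfg2)
  truth2 <- labelArray(groundTruth(geom2, cfg2)$labels) == 1L
  m2 <- segmentHydrogel(stk2)
  expect_gte(sum(m2 & truth2) / sum(truth2), 0.95)

  # five isolated sub-threshold blobs leave the final mask unchanged
  cw <- channel(stk2, "cw")
  corners <- list(c(3, 3, 40), c(3, 98, 40), c(98, 3, 40), c(98, 98, 40),
                  c(3, 50, 48))
  for (p in corners)
    cw[p[1]:(p[1] + 1), p[2]:(p[2] + 1), p[3]:(p[3] + 1)] <- fld@cwShell
  stk2b <- channelStack(cw, channel(stk2, "af594"), channel(stk2, "fitc"), 1)
  expect_identical(segmentHydrogel(stk2b), m2)

  dark <- channelStack(array(0, dim = dim(cw)), channel(stk2, "af594"),
                       channel(stk2, "fitc"), 1)
  expect_error(segmentHydrogel(dark), "no hydrogel detected")
})

test_that("segmentCoupon finds the reflection plane and biases toward coupon", {
  sc <- smallScene()
  stk <- renderStack(sc$geom, sc$fld, sc$cfg)
  p0 <- segmentationParams(couponBiasLayers = 0L)
  m0 <- segmentCoupon(stk, p0)
  planes <- attr(m0, "planes")
  # reflection layer = topmost coupon layer = z-index 2 (couponZ = 2, dz = 1)
  expect_true(all(planes == 2L))
  # bias makes the mask a strict superset
  m2 <- segmentCoupon(stk, segmentationParams(couponBiasLayers = 2L))
  expect_true(all(m0[m2 == FALSE] == FALSE))
  expect_true(all(m2[m0]))
  expect_gt(sum(m2), sum(m0))

  # noisy detection: sd = 10% of the reflection amplitude, >= 95% of columns
  # within +/- 1 layer
  cfgN <- imagingConfig(dim = rep(64L, 3), voxelSize = 1,
                        noiseModel = noiseGaussian(0.1 * sc$fld@couponReflection),
                        seed = 3)
  stkN <- renderStack(sc$geom, sc$fld, cfgN)
  pN <- attr(segmentCoupon(stkN, p0), "planes")
  expect_gte(mean(abs(pN - 2L) <= 1L), 0.95)

  # a stack with no coupon at all
  flat <- channelStack(channel(stk, "cw"), channel(stk, "af594"),
                       array(100, dim = dim(channel(stk, "fitc"))), 1)
  expect_error(segmentCoupon(flat), "coupon not found")
})

test_that("assignDomains applies precedence and yields a partition", {
  d <- c(8L, 8L, 8L)
  e <- array(FALSE, dim = d)
  allw <- assignDomains(e, e, e)
  expect_true(all(labelArray(allw) == DOMAIN_CODES[["water"]]))

  one <- e; one[3, 3, 3] <- TRUE
  lab <- assignDomains(one, one, one)     # in all three masks -> coupon
  expect_equal(labelArray(lab)[3, 3, 3], DOMAIN_CODES[["coupon"]])
  lab2 <- assignDomains(one, one, e)      # sphere beats hydrogel
  expect_equal(labelArray(lab2)[3, 3, 3], DOMAIN_CODES[["microsphere"]])

  expect_error(assignDomains(e, e, array(FALSE, dim = c(4L, 4L, 4L))),
               "share one shape")
  expect_equal(sum(domainCounts(lab)), prod(d))
})

test_that("end-to-end segmentation agrees with ground truth on noise-free phantoms", {
  sc <- smallScene(kp = 0.7)
  gt <- groundTruth(sc$geom, sc$cfg, sc$fld)
  stk <- renderStack(sc$geom, sc$fld, sc$cfg)
  seg <- suppressWarnings(segmentStack(stk))
  acc <- mean(labelArray(seg) == labelArray(gt$labels))
  expect_gte(acc, 0.98)
  expect_equal(sum(domainCounts(seg)), prod(sc$cfg@dim))
})

test_that("segmentation accuracy degrades gracefully with noise", {
  sc <- smallScene(kp = 0.7)
  gt <- labelArray(groundTruth(sc$geom, sc$cfg, sc$fld)$labels)
  accAt <- function(sd) {
    mean(vapply(1:3, function(s) {
      cfg <- imagingConfig(dim = rep(64L, 3), voxelSize = 1,
                           noiseModel = noiseGaussian(sd), seed = s)
      stk <- renderStack(sc$geom, sc$fld, cfg)
      mean(labelArray(suppressWarnings(segmentStack(stk))) == gt)
    }, numeric(1)))
  }
  a5 <- accAt(5); a20 <- accAt(20)
  expect_gte(a5, 0.95)
  expect_lte(a20, a5 + 1e-9)    # monotone on average over seeds
})
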