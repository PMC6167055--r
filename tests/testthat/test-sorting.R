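test_that("sorting ratio definition and the S = 0 convention", {
  m <- sortingMeasurement(50, 100, 40, 80)    # equal channel ratios
  expect_equal(sortingRatio(m), 1)
  m2 <- sortingMeasurement(100, 100, 40, 80)
  expect_equal(sortingRatio(m2), 2)
  # below-detection tube protein signal forces S = 0
  mBd <- sortingMeasurement(1, 100, 40, 80, belowDetection = TRUE)
  expect_identical(sortingRatio(mBd), 0)
  expect_error(sortingMeasurement(50, 0, 40, 80), "vesicle intensities")
})

test_that("S is invariant to per-channel gain given correct background subtraction", {
  m <- sortingMeasurement(30, 90, 20, 60, phiV = 1)
  s0 <- sortingRatio(m)
  for (g in c(0.2, 5)) {
    mg <- sortingMeasurement(30 * g, 90 * g, 20, 60)
    expect_equal(sortingRatio(mg), s0, tolerance = 1e-12)
    mh <- sortingMeasurement(30, 90, 20 * g, 60 * g)
    expect_equal(sortingRatio(mh), s0, tolerance = 1e-12)
  }
})

test_that("the three radius routes obey their closed forms and inverses", {
  # tension route: R = sqrt(kappa/(2 sigma)); kappa = 2 sigma R^2 inverts it
  R0 <- 50e-9
  sigma <- 7e-5
  expect_equal(radiusFromTension(2 * sigma * R0^2, sigma), 50, tolerance = 1e-12)
  expect_equal(radiusFromTension(85 * kBT_J, 7e-5), 50, tolerance = 0.01)
  # quadrupling tension halves the radius
  expect_equal(radiusFromTension(85 * kBT_J, 4 * 7e-5),
               radiusFromTension(85 * kBT_J, 7e-5) / 2, tolerance = 1e-12)
  # force route: R = f/(4 pi sigma); f = 4 pi sigma R inverts it
  expect_equal(radiusFromForce(4 * pi * sigma * R0, sigma), 50, tolerance = 1e-12)
  expect_equal(radiusFromForce(12.57e-12, 5e-5), 20, tolerance = 0.001)
  expect_error(radiusFromForce(1e-12, 0), "> 0")
  # fluorescence route
  expect_equal(radiusFromFluorescence(0.5, Rc = 200), 100)
  expect_equal(radiusFromFluorescence(0.1, Rc = 312), 31.2)
  r <- radiusFromFluorescence(0.3, Rc = 200, RcSd = 50)
  expect_equal(attr(r, "sd"), 15)
  # all three agree on self-consistent synthetic data
  sig <- c(2e-5, 5e-5, 2e-4)
  R <- c(80, 40, 25)            # nm
  kap <- 2 * sig * (R * 1e-9)^2
  f <- 4 * pi * sig * (R * 1e-9)
  ratio <- R / 200
  expect_equal(radiusFromTension(kap[2], sig[2]), R[2], tolerance = 1e-9)
  expect_equal(radiusFromForce(f, sig), R, tolerance = 1e-9)
  expect_equal(radiusFromFluorescence(ratio, 200), R, tolerance = 1e-9)
})

test_that("Rc calibration fit recovers the slope with its SD", {
  # exact collinear pairs: slope recovered, SD 0
  expect_equal(fitRc(c(0.1, 0.3, 0.5), 250 * c(0.1, 0.3, 0.5))$Rc, 250)
  expect_equal(fitRc(c(0.2, 0.4), 312 * c(0.2, 0.4))$sd, 0)
  expect_error(fitRc(c(0, 0, 0), c(1, 2, 3)), "degenerate")
  # pairs built from force-route radii round-trip the generator slope
  set.seed(21)
  sig <- runif(50, 2e-5, 3e-4)
  Rtrue <- radiusFromForce(4 * pi * sig * runif(50, 15e-9, 90e-9), sig)
  ratio <- Rtrue / 200
  expect_equal(fitRc(ratio, Rtrue)$Rc, 200, tolerance = 1e-9)
  # 10% radius noise: recovery within the printed +/- 10 nm
  noisy <- Rtrue * (1 + rnorm(50, 0, 0.1))
  expect_lt(abs(fitRc(ratio, noisy)$Rc - 200), 10)
})

test_that("coverage binning groups half-open bins and excludes S = 0 from dispersion", {
  phiV <- c(1, 1.9, 2, 4.9, 5, 30, -1)
  S <- c(1.5, 0, 2, 2.5, 3, 3.5, 1)
  out <- binByCoverage(phiV, S)
  expect_identical(out$bin, c("[0,2)", "[2,5)", "[5,Inf)", "unbinned"))
  expect_equal(out$n, c(2L, 2L, 2L, 1L))
  b1 <- out[out$bin == "[0,2)", ]
  expect_equal(b1$nBelowDetection, 1L)
  expect_equal(b1$meanS, 1.5)          # the S = 0 entry is excluded
  expect_error(binByCoverage(1, 1, binEdges = c(2, 1)), "increasing")
  # an all-S=0 bin yields NA dispersion and a full below-detection count
  out0 <- binByCoverage(c(1, 1), c(0, 0))
  expect_equal(out0$nBelowDetection[1], 2L)
  expect_true(is.na(out0$meanS[1]))
  # simulated S ~ N(2, 0.3) in one bin: mean within 2 SE of 2
  set.seed(31)
  Ssim <- rnorm(200, 2, 0.3)
  outS <- binByCoverage(rep(1, 200), Ssim)
  expect_lt(abs(outS$meanS[1] - 2), 2 * 0.3 / sqrt(200))
})

test_that("rendered low-coverage scene recovers S = 1.2 within 10%", {
  # 1% coverage at 20 nm^2 footprint is 500 molecules/um^2
  s <- quickScene(tubeRatioMembrane = 0.4, sortingTrue = 1.2,
                  proteinDensity = densityFromFraction(1, 20),
                  psfSigma = 1, noiseSd = 2, seed = 12L)
  m <- measureSceneSorting(s)
  expect_equal(sortingRatio(m), 1.2, tolerance = 0.1 / 1.2)
})

test_that("the I-BAR ratio anchor is explicit and provenance-tagged", {
  r <- ibarRatioToRadius(0.4)
  expect_equal(as.numeric(r), 30)
  expect_match(attr(r, "provenance"), "anchor")
  expect_equal(as.numeric(ibarRatioToRadius(0.3)), 22.5, tolerance = 0.2)
})
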