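test_that("titration simulation evaluates the hyperbola exactly without noise", {
  # midpoint: C = Kd gives phiMax/2; C = 0 gives 0
  tt <- TitrationTruth(phiMax = 12, kd = 1.2, concentrations = c(0, 1.2, 4),
                       noiseCv = 0)
  d <- simulateTitration(tt)
  expect_equal(d$phi[1], 0)
  expect_equal(d$phi[2], 6)
  expect_equal(d$phi[3], 12 * 4 / 5.2)   # 9.2308 by direct evaluation
})

test_that("simulators are bit-identical under the same seed", {
  tt <- TitrationTruth(noiseCv = 0.1, seed = 42L)
  expect_identical(simulateTitration(tt), simulateTitration(tt))
  ft <- FrapTruth(noiseSd = 5, seed = 42L)
  expect_identical(as.data.frame(simulateFrap(ft)), as.data.frame(simulateFrap(ft)))
  sc <- SyntheticScene(noiseSd = 2, seed = 42L)
  expect_identical(channelImage(renderScene(sc), "protein"),
                   channelImage(renderScene(sc), "protein"))
  expect_identical(simulateClassCounts(c(0.5, 0.3, 0.2), 60, seed = 7L),
                   simulateClassCounts(c(0.5, 0.3, 0.2), 60, seed = 7L))
})

test_that("FRAP simulation has the stated limits", {
  # immobile: flat at 0 after correction
  flat <- correctAndNormalize(simulateFrap(FrapTruth(mobileFraction = 0,
                                                     noiseSd = 0)))
  expect_equal(flat$recovery, rep(0, 60))
  # fully mobile, t >> tau, no bleach/noise: corrected recovery -> 1
  full <- correctAndNormalize(simulateFrap(
    FrapTruth(mobileFraction = 1, recoveryTau = 2, acqBleachRate = 0,
              nFrames = 100L, frameInterval = 1, noiseSd = 0)))
  expect_equal(tail(full$recovery, 1), 1, tolerance = 1e-8)
  # acquisition bleaching cancels exactly in the corrected curve
  noBleach <- correctAndNormalize(simulateFrap(
    FrapTruth(mobileFraction = 0.4, acqBleachRate = 0, noiseSd = 0)))
  withBleach <- correctAndNormalize(simulateFrap(
    FrapTruth(mobileFraction = 0.4, acqBleachRate = 0.02, noiseSd = 0)))
  expect_equal(withBleach$recovery, noBleach$recovery, tolerance = 1e-12)
})

test_that("tether-series angles follow the force balance", {
  sig <- seq(0.05, 0.25, by = 0.05)
  # gamma = 0: no adhesion, theta = 0
  d0 <- simulateTetherSeries(TetherTruth(gammaTrue = 0), sig)
  expect_equal(d0$theta, rep(0, 5))
  # gamma = sigma/2: cos(theta) = 1/2, theta = 60 degrees
  d <- simulateTetherSeries(TetherTruth(gammaTrue = 0.5 * mNm_to_Nm(0.1),
                                        sigmaTest = 0.1),
                            sigmas = 0.1)
  expect_equal(d$theta, pi / 3, tolerance = 1e-12)
  # impossible geometry rejected
  expect_error(simulateTetherSeries(TetherTruth(gammaTrue = 4e-5,
                                                sigmaTest = 0.05),
                                    sigmas = c(0.03)),
               "impossible geometry")
  expect_error(TetherTruth(gammaTrue = 1e-4, sigmaTest = 0.05), "gammaTrue")
})

test_that("class-count simulation is multinomial with the stated means", {
  expect_identical(unname(simulateClassCounts(c(1, 0, 0), 60)),
                   c(60L, 0L, 0L))
  expect_identical(unname(simulateClassCounts(c(0.3, 0.7), 0)), c(0L, 0L))
  expect_error(simulateClassCounts(c(0.5, 0.5), -1), "nTubes")
  expect_error(simulateClassCounts(c(0.5, 0.4), 10), "sum to 1")
  # law of large numbers: mean counts over many draws approach n * p
  p <- c(0.685, 0.065, 0.25)
  draws <- vapply(seq_len(1000),
                  function(i) simulateClassCounts(p, 60, seed = i),
                  integer(3))
  expect_lt(max(abs(rowMeans(draws) - 60 * p)), 0.5)   # ~(41.1, 3.9, 15)
})

test_that("scene rendering encodes the stated ratios and rejects bad geometry", {
  # noiseless, unblurred scene: measured ratios equal ground truth
  s <- quickScene(tubeRatioMembrane = 0.4, sortingTrue = 1, psfSigma = 0,
                  noiseSd = 0)
  m <- measureSceneSorting(s)
  expect_equal(sortingRatio(m), 1, tolerance = 1e-6)   # S = 1 by construction
  expect_equal(m@iTubeMembrane / m@iVesMembrane, 0.4, tolerance = 0.025)
  # geometry errors
  expect_error(renderScene(SyntheticScene(guvRadius = 10, imageSize = 64L)),
               "radius exceeds frame")
  expect_error(renderScene(SyntheticScene(guvRadius = 6.5, imageSize = 160L)),
               "tube longer than image")
  # tube-less scene: tube quantification raises, vesicle ROI still works
  g <- quickScene(sceneKind = "guv_only")
  expect_error(measureSceneSorting(g), "no tube ROI")
  expect_gt(as.numeric(measureVesicleIntensity(g)), 0)
})

test_that("sorting recovery through the image pipeline hits ground truth", {
  # S = 8 at moderate blur and low noise recovered within 10%
  s <- quickScene(tubeRatioMembrane = 0.4, sortingTrue = 8, psfSigma = 1,
                  noiseSd = 2, seed = 11L)
  expect_equal(sortingRatio(measureSceneSorting(s)), 8, tolerance = 0.1)
})

test_that("rendering is linear in channel gain and leaves S unchanged", {
  s1 <- quickScene(gainProtein = 1, noiseSd = 0, psfSigma = 1)
  s2 <- quickScene(gainProtein = 2, noiseSd = 0, psfSigma = 1)
  r <- sceneRois(s1)
  p1 <- peakMinusBackground(extractProfile(channelImage(s1, "protein"), r$tube), "rect")
  p2 <- peakMinusBackground(extractProfile(channelImage(s2, "protein"), r$tube), "rect")
  expect_equal(as.numeric(p2) / as.numeric(p1), 2, tolerance = 1e-9)
  expect_equal(sortingRatio(measureSceneSorting(s2)),
               sortingRatio(measureSceneSorting(s1)), tolerance = 1e-9)
})

test_that("two-GUV contact scenes render and their background is recoverable", {
  s <- quickScene(sceneKind = "two_guv_contact", guvRadius = 3,
                  backgroundLevel = 50, noiseSd = 1.5, seed = 5L)
  pr <- extractProfile(channelImage(s, "protein"), sceneRois(s)$vesicle)
  expect_lt(abs(backgroundRect(pr) - 50), 1.5)   # within noise of true level
})
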