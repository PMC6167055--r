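test_that("adhesion energy follows the contact force balance", {
  expect_equal(gammaFromAngle(0.1, 0), 0)                 # no adhesion
  expect_equal(gammaFromAngle(0.1, pi / 3), 5e-5)         # cos 60 deg = 1/2
  expect_error(gammaFromAngle(0.1, pi / 2), "range")
  expect_error(gammaFromAngle(0, 0.1), "> 0")
  # gamma in [0, sigma) and increasing in theta
  th <- seq(0, pi / 2 - 0.01, length.out = 50)
  g <- gammaFromAngle(0.2, th)
  expect_true(all(diff(g) > 0))
  expect_true(all(g >= 0 & g < mNm_to_Nm(0.2)))
})

test_that("generator angles and gammaFromAngle are exact inverses", {
  sig <- seq(0.05, 0.25, by = 0.02)
  truth <- TetherTruth(gammaTrue = 5e-6, angleNoiseSd = 0)
  d <- simulateTetherSeries(truth, sig)
  expect_equal(gammaFromAngle(d$sigma, d$theta), rep(5e-6, length(sig)),
               tolerance = 1e-12)
})

test_that("per-bond energy arithmetic and scaling", {
  expect_equal(energyPerBond(4.11e-6, 1000), 1)   # unit arithmetic: 1 kBT
  expect_equal(energyPerBond(4.11e-6, 2000), 0.5) # doubling density halves E
  expect_error(energyPerBond(1e-6, 0), "> 0")
  expect_error(energyPerBond(1e-6, 100, efficiency = 0), "efficiency")
  # dimensional bridge: (J/m^2)/(1/um^2) -> J carries 1e-12
  expect_equal(areal_energy_per_molecule(1, 1), 1e-12)
})

test_that("full bond-energy chain recovers the generator within 10%", {
  cal <- unitCal(A = 2, brightnessRatio = 1.5, labelingDegree = 0.9)
  truth <- TetherTruth(gammaTrue = 5e-6, nPairsPerArea = 1000,
                       angleNoiseSd = 0.002, seed = 14L)
  sig <- seq(0.05, 0.25, by = 0.05)
  d <- simulateTetherSeries(truth, sig, calibration = cal)
  res <- lapply(seq_len(nrow(d)), function(i) {
    tg <- tetherGeometry(sigmaTest = d$sigma[i], theta = d$theta[i],
                         contactArea = 3, proteinIntensity = d$protein_intensity[i],
                         calibration = cal)
    bondEnergy(tg, dimer = TRUE)
  })
  eTrue <- energyPerBond(5e-6, 1000)
  eHat <- vapply(res, `[[`, numeric(1), "energyPerBond_kBT")
  expect_lt(max(abs(eHat - eTrue) / eTrue), 0.1)
  expect_equal(res[[1]]$bondDensity, 1000, tolerance = 1e-12)
})

test_that("tension series are summarised with a monotonic-trend statistic", {
  one <- tensionSeriesSummary(0.1, 2e-6, 0.5)
  expect_equal(nrow(one$table), 1L)
  expect_equal(one$table$medianGamma, 2e-6)
  # constant gamma across tensions: flat summary, zero trend
  flat <- tensionSeriesSummary(c(0.05, 0.1, 0.2), rep(3e-6, 3), rep(1, 3))
  expect_equal(flat$trend, 0)
  # generator with gamma increasing in sigma: positive trend recovered
  sig <- seq(0.02, 0.25, length.out = 12)
  gam <- 2e-5 * sig + 1e-7 * seq_along(sig)   # strictly increasing
  up <- tensionSeriesSummary(sig, gam, gam / 1e-6)
  expect_gt(up$trend, 0.9)
})

test_that("contact angle is recovered from clicked contour points", {
  # circle of radius 10 centred at origin; contact chord at distance
  # d = 10*cos(40deg) from centre gives theta = 40 degrees
  thTrue <- 40 * pi / 180
  ang <- seq(0.3, 2.8, length.out = 12)
  contour <- cbind(10 * cos(ang), 10 * sin(ang))
  half <- 10 * sin(thTrue)
  yc <- -10 * cos(thTrue)
  contact <- rbind(c(-half, yc), c(half, yc))
  expect_equal(contactAngleFromPoints(contour, contact), thTrue,
               tolerance = 1e-6)
  expect_error(contactAngleFromPoints(contour[1:2, ], contact), ">= 3")
  expect_error(contactAngleFromPoints(contour, rbind(c(-20, 0), c(20, 0))),
               "wider")
})

test_that("a low reference tension triggers the sphericity warning", {
  expect_warning(tetherGeometry(0.05, 0.3, 3, 10, unitCal(),
                                referenceTension = 0.2), "0.4 mN/m")
})
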