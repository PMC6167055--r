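test_that("profile extraction reduces to raw pixels for axis-aligned unit-width ROIs", {
  img <- matrix(seq_len(40 * 40), 40, 40)
  roi <- rectRoi(c(10, 3), c(10, 38), width = 1)
  pr <- extractProfile(img, roi)
  expect_equal(profileValues(pr), img[3:38, 10])
  # constant image gives a flat profile at that constant
  flat <- extractProfile(matrix(7, 40, 40), rectRoi(c(5, 2), c(35, 2), width = 3))
  expect_equal(profileValues(flat), rep(7, 31))
  # out-of-bounds and degenerate ROIs are rejected
  expect_error(extractProfile(img, rectRoi(c(1, 1), c(1, 39), width = 5)),
               "out of bounds")
  expect_error(extractProfile(img, rectRoi(c(10, 10), c(10, 10.2))),
               "degenerate")
})

test_that("oblique ROIs agree with axis-aligned ones on smooth images", {
  # linear ramp: mean across a symmetric width equals the centreline value
  img <- outer(seq_len(60), seq_len(60), function(y, x) 2 * x + 3 * y)
  diag <- extractProfile(img, rectRoi(c(10, 10), c(40, 40), width = 5))
  expected <- 2 * (10 + profilePositions(diag) / sqrt(2)) +
              3 * (10 + profilePositions(diag) / sqrt(2))
  expect_equal(profileValues(diag), expected, tolerance = 1e-10)
})

test_that("the three background rules implement their edge conventions", {
  p <- stepProfile()
  expect_equal(backgroundRect(p), 2)         # (mean first 15 + mean last 15)/2
  expect_equal(backgroundTop(p), 1)          # mean of first 15 only
  p10 <- intensityProfile(c(rep(1, 10), 9, rep(3, 10)))
  expect_equal(backgroundLine(p10), 2)       # pooled first/last 10
  flat <- intensityProfile(rep(4.2, 40))
  expect_equal(backgroundRect(flat), 4.2)
  expect_equal(backgroundTop(flat), 4.2)
  expect_equal(backgroundLine(flat), 4.2)
  expect_error(backgroundRect(intensityProfile(rep(1, 20))), "too short")
  expect_error(backgroundLine(intensityProfile(rep(1, 15))), "too short")
  expect_error(backgroundTop(intensityProfile(rep(1, 5))), "too short")
})

test_that("peak minus background subtracts the rule value and flags noise-level peaks", {
  expect_equal(as.numeric(peakMinusBackground(stepProfile(), "rect")), 7)  # 9 - 2
  # pure-noise profile is flagged below detection
  set.seed(1)
  noise <- intensityProfile(rnorm(41, 100, 1))
  expect_true(attr(peakMinusBackground(noise, "rect"), "belowDetection"))
  # strong peak is not flagged
  expect_false(attr(peakMinusBackground(stepProfile(), "rect"), "belowDetection"))
})

test_that("gain scales and offsets cancel in peak-minus-background", {
  set.seed(2)
  base <- c(rep(10, 15), 10 + 50 * exp(-(-8:8)^2 / 4), rep(10, 15)) + rnorm(47, 0, 0.3)
  p <- intensityProfile(base)
  for (rule in c("rect", "top", "line")) {
    v0 <- as.numeric(peakMinusBackground(p, rule))
    for (g in c(0.5, 3, 17)) {
      expect_equal(as.numeric(peakMinusBackground(intensityProfile(g * base), rule)),
                   g * v0, tolerance = 1e-12)
    }
    for (off in c(-5, 100, 1e4)) {
      expect_equal(as.numeric(peakMinusBackground(intensityProfile(base + off), rule)),
                   v0, tolerance = 1e-9)
    }
  }
  # rect and line rules agree on symmetric flat-background profiles
  expect_equal(backgroundRect(p), backgroundLine(p), tolerance = 0.05)
})

test_that("profile peak lands on the rendered membrane position", {
  s <- quickScene(psfSigma = 1, noiseSd = 1, seed = 3L)
  r <- sceneRois(s)
  pr <- extractProfile(channelImage(s, "membrane"), r$tube)
  truthY <- groundTruth(s)$tubeY
  roiStartY <- r$tube@endpoints[1, 2]
  peakY <- roiStartY + profilePositions(pr)[which.max(profileValues(pr))]
  expect_lt(abs(peakY - truthY), 1)
})

test_that("extracted ratios match generator truth on noiseless scenes", {
  # oracle equivalence: <= 1% after PSF blur <= 1 px (ratio of identical
  # line cross-sections is blur-invariant up to curvature effects)
  for (ratio in c(0.2, 0.5, 1)) {
    s <- quickScene(tubeRatioMembrane = ratio, sortingTrue = 2.5,
                    psfSigma = 1, noiseSd = 0)
    m <- measureSceneSorting(s)
    expect_equal(sortingRatio(m), 2.5, tolerance = 0.01)
  }
})

test_that("in-focus frame selection picks the sharpest tube image", {
  scenes <- lapply(c(3, 1, 2), function(sig)
    quickScene(psfSigma = sig, noiseSd = 1, seed = 8L))
  frames <- lapply(scenes, channelImage, channel = "membrane")
  expect_identical(selectInFocusFrame(frames, sceneRois(scenes[[1]])$tube), 2L)
  expect_error(selectInFocusFrame(list(), rectRoi(c(1, 1), c(1, 30))), "empty")
})

test_that("normalized line profiles run 0 to 1 with distance 0 at the tip", {
  ramp <- outer(seq_len(50), seq_len(50), function(y, x) x)
  out <- normalizedLineProfile(list(ch1 = ramp), cbind(c(5, 45), c(25, 25)))
  expect_equal(out$distance[1], 0)
  expect_equal(range(out$ch1), c(0, 1))
  expect_equal(out$ch1, (out$distance) / max(out$distance), tolerance = 1e-10)
  # constant channel is degenerate: zeros plus a flag
  const <- matrix(5, 50, 50)
  out2 <- normalizedLineProfile(list(a = const, b = ramp),
                                cbind(c(5, 45), c(25, 25)))
  expect_identical(attr(out2, "degenerate"), "a")
  expect_true(all(out2$a == 0))
  expect_error(normalizedLineProfile(list(a = ramp), cbind(c(5, 5), c(25, 25))),
               "zero-length")
})
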