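#' @include AllClasses.R AllGenerics.R
NULL

#' A rendered two-channel scene with its ground truth
#'
#' Holds the membrane-dye and protein channel images (numeric matrices,
#' rows = y, cols = x) together with the generating [SyntheticScene] and a
#' ground-truth record of the ideal (pre-blur, pre-noise) peak intensities
#' and ratios.
#'
#' @slot membrane,protein channel images, a.u.
#' @slot truth list of ground-truth geometry and intensity values.
#' @slot scene the generating [SyntheticScene].
#' @export
setClass("RenderedScene",
  representation(membrane = "matrix", protein = "matrix",
                 truth = "list", scene = "SyntheticScene"))

#' @describeIn RenderedScene ground-truth record of the generator
#' @param x a `RenderedScene`
#' @export
setMethod("groundTruth", "RenderedScene", function(x) x@truth)

#' @describeIn RenderedScene extract one channel image
#' @param channel `"membrane"` or `"protein"`
#' @export
setMethod("channelImage", "RenderedScene", function(x, channel) {
  channel <- match.arg(channel, c("membrane", "protein"))
  slot(x, channel)
})

setMethod("show", "RenderedScene", function(object) {
  cat("RenderedScene:", object@scene@sceneKind, "\n",
      sprintf("  %d x %d px, pixel size %.3g um\n",
              nrow(object@membrane), ncol(object@membrane),
              object@scene@pixelSize),
      sprintf("  truth: (Itube/Ives)membrane = %.3g, S = %.3g\n",
              object@scene@tubeRatioMembrane, object@scene@sortingTrue))
})

#' Construct a synthetic scene description
#'
#' Convenience constructor for [SyntheticScene-class]; see that class for the
#' meaning and defaults of every parameter. Defaults describe a 4-um GUV in a
#' 160x160 px frame at 0.1 um/px with a pulled tube whose membrane-dye
#' tube/vesicle ratio is 0.4 (i.e. a tube radius of about 80 nm at the
#' BODIPY TR calibration).
#'
#' @param sceneKind `"guv_with_tube"`, `"two_guv_contact"` or `"guv_only"`
#' @param guvRadius GUV radius, um
#' @param tubeRatioMembrane ground-truth membrane-dye tube/vesicle ratio
#' @param sortingTrue ground-truth sorting ratio S
#' @param proteinDensity vesicle protein density, molecules/um^2
#' @param psfSigma PSF sigma, px
#' @param backgroundLevel additive background, a.u.
#' @param noiseSd additive Gaussian noise SD, a.u.
#' @param gainMembrane,gainProtein channel gains, a.u. per unit density
#' @param pixelSize um per px
#' @param imageSize frame side, px
#' @param seed RNG seed
#' @return a [SyntheticScene-class] object
#' @export
SyntheticScene <- function(sceneKind = "guv_with_tube", guvRadius = 4,
                           tubeRatioMembrane = 0.4, sortingTrue = 1,
                           proteinDensity = 500, psfSigma = 1,
                           backgroundLevel = 100, noiseSd = 2,
                           gainMembrane = 1, gainProtein = 1,
                           pixelSize = 0.1, imageSize = 160L, seed = 1L) {
  new("SyntheticScene", sceneKind = sceneKind, guvRadius = guvRadius,
      tubeRatioMembrane = tubeRatioMembrane, sortingTrue = sortingTrue,
      proteinDensity = proteinDensity, psfSigma = psfSigma,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      gainMembrane = gainMembrane, gainProtein = gainProtein,
      pixelSize = pixelSize, imageSize = as.integer(imageSize),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene:", object@sceneKind, "\n",
      sprintf("  GUV radius %.3g um, (Itube/Ives)membrane = %.3g, S = %.3g\n",
              object@guvRadius, object@tubeRatioMembrane, object@sortingTrue),
      sprintf("  PSF %.3g px, background %.3g, noise SD %.3g, seed %d\n",
              object@psfSigma, object@backgroundLevel, object@noiseSd,
              object@seed))
})

# Membrane-dye surface density used by the renderer (molecules/um^2); the
# membrane channel's vesicle peak is gainMembrane * this constant.
.MEMBRANE_DYE_DENSITY <- 1000

# Line width (Gaussian sigma, px) of membrane structures before PSF blur;
# the same cross-section is used for vesicle contour and tube so that blur
# rescales both peaks identically and tube/vesicle ratios survive the optics.
.LINE_SIGMA <- 0.7

# Separable Gaussian blur with zero padding; sigma in px.
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  convRows <- function(m) {
    n <- ncol(m)
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[, which(ok)] <- out[, which(ok)] + k[j] * m[, src[ok]]
    }
    out
  }
  t(convRows(t(convRows(img))))
}

# Distance-based Gaussian cross-section membrane structures on a pixel grid.
.ringImage <- function(nx, ny, cx, cy, radius, peak, lineSigma = .LINE_SIGMA) {
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  y <- matrix(seq_len(ny), ny, nx)
  d <- sqrt((x - cx)^2 + (y - cy)^2) - radius
  peak * exp(-d^2 / (2 * lineSigma^2))
}

.segmentImage <- function(nx, ny, x0, x1, ycenter, peak, lineSigma = .LINE_SIGMA) {
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  y <- matrix(seq_len(ny), ny, nx)
  dy <- abs(y - ycenter)
  inx <- (x >= x0) & (x <= x1)
  peak * exp(-dy^2 / (2 * lineSigma^2)) * inx
}

#' Render a two-channel confocal-like equatorial section
#'
#' Draws the GUV contour as an anti-aliased circle and, for
#' `"guv_with_tube"`, the nanotube as a straight horizontal segment from the
#' GUV edge to the frame margin. Pre-blur peak intensities are: vesicle
#' membrane = `gainMembrane` x 1000 (the fixed membrane-dye density,
#' molecules/um^2), tube membrane = vesicle membrane x `tubeRatioMembrane`;
#' vesicle protein = `gainProtein * proteinDensity`,
#' tube protein = vesicle protein x `tubeRatioMembrane * sortingTrue`.
#' The structures are PSF-blurred, Gaussian noise is added, then the constant
#' background offset. `"two_guv_contact"` draws two touching circles.
#'
#' @param scene a [SyntheticScene-class]
#' @return a [RenderedScene-class]
#' @export
renderScene <- function(scene) {
  validObject(scene)
  n <- scene@imageSize
  rpx <- scene@guvRadius / scene@pixelSize
  margin <- 6
  cy <- n / 2
  vesMem <- scene@gainMembrane * .MEMBRANE_DYE_DENSITY
  vesProt <- scene@gainProtein * scene@proteinDensity

  if (scene@sceneKind == "two_guv_contact") {
    if (4 * rpx + 2 * margin > n)
      stop("GUV radius exceeds frame: two GUVs of radius ", round(rpx),
           " px do not fit in ", n, " px")
    cx1 <- n / 2 - rpx
    cx2 <- n / 2 + rpx
    mem <- pmax(.ringImage(n, n, cx1, cy, rpx, vesMem),
                .ringImage(n, n, cx2, cy, rpx, vesMem))
    prot <- pmax(.ringImage(n, n, cx1, cy, rpx, vesProt),
                 .ringImage(n, n, cx2, cy, rpx, vesProt))
    geom <- list(centers = rbind(c(cx1, cy), c(cx2, cy)), radiusPx = rpx)
  } else {
    cx <- margin + rpx + 1
    if (cx + rpx > n - margin && scene@sceneKind == "guv_only")
      stop("GUV radius exceeds frame: radius ", round(rpx), " px in ", n, " px")
    if (2 * rpx + 2 * margin > n)
      stop("GUV radius exceeds frame: radius ", round(rpx), " px in ", n, " px")
    mem <- .ringImage(n, n, cx, cy, rpx, vesMem)
    prot <- .ringImage(n, n, cx, cy, rpx, vesProt)
    geom <- list(centers = rbind(c(cx, cy)), radiusPx = rpx)
    if (scene@sceneKind == "guv_with_tube") {
      x0 <- cx + rpx
      x1 <- n - margin
      if (x1 - x0 < 20)
        stop("tube longer than image allows: only ", round(x1 - x0),
             " px remain right of the GUV; enlarge imageSize or shrink guvRadius")
      tubeMem <- vesMem * scene@tubeRatioMembrane
      tubeProt <- vesProt * scene@tubeRatioMembrane * scene@sortingTrue
      mem <- pmax(mem, .segmentImage(n, n, x0, x1, cy, tubeMem))
      prot <- pmax(prot, .segmentImage(n, n, x0, x1, cy, tubeProt))
      geom$tubeX <- c(x0, x1)
      geom$tubeY <- cy
    }
  }

  mem <- gaussianBlur(mem, scene@psfSigma)
  prot <- gaussianBlur(prot, scene@psfSigma)
  withSeed(scene@seed, {
    mem <- mem + matrix(rnorm(n * n, 0, scene@noiseSd), n, n)
    prot <- prot + matrix(rnorm(n * n, 0, scene@noiseSd), n, n)
  })
  mem <- mem + scene@backgroundLevel
  prot <- prot + scene@backgroundLevel

  truth <- c(geom, list(
    vesiclePeakMembrane = vesMem,
    vesiclePeakProtein = vesProt,
    tubeRatioMembrane = scene@tubeRatioMembrane,
    sortingTrue = scene@sortingTrue,
    proteinDensity = scene@proteinDensity,
    backgroundLevel = scene@backgroundLevel,
    noiseSd = scene@noiseSd
  ))
  new("RenderedScene", membrane = mem, protein = prot, truth = truth,
      scene = scene)
}

#' Standard ROIs for a rendered scene, from its ground-truth geometry
#'
#' ROI placement is always an explicit input to quantification (mirroring
#' manual ROI drawing); for rendered scenes this helper derives the tube and
#' vesicle ROIs from the known geometry: a vertical profile axis across the
#' tube midpoint and another across the vesicle contour at the bottom of the
#' GUV, away from the tube attachment.
#'
#' @param rendered a [RenderedScene-class]
#' @param halfLength profile half-length, px
#' @param width averaging width, px
#' @return list with elements `vesicle` and `tube` ([RectRoi][Roi]); `tube`
#'   is `NULL` for scenes without a tube, and tube-profile extraction on such
#'   scenes raises a "no tube ROI" error downstream
#' @export
sceneRois <- function(rendered, halfLength = 25, width = 10) {
  tr <- rendered@truth
  cx <- tr$centers[1, 1]
  cy <- tr$centers[1, 2]
  rpx <- tr$radiusPx
  yv <- cy + rpx                      # bottom of the GUV contour
  vesicle <- rectRoi(c(cx, yv - halfLength), c(cx, yv + halfLength),
                     width = width)
  tube <- NULL
  if (!is.null(tr$tubeX)) {
    xm <- mean(tr$tubeX)
    tube <- rectRoi(c(xm, tr$tubeY - halfLength), c(xm, tr$tubeY + halfLength),
                    width = width)
  }
  list(tube = tube, vesicle = vesicle)
}

#' Simulate a binding titration from a hyperbolic ground truth
#'
#' phi_i = phiMax * C_i / (C_i + Kd) * (1 + eps_i) with eps_i ~ N(0, noiseCv);
#' deterministic under the truth's seed.
#'
#' @param truth a [TitrationTruth-class]
#' @return data.frame with columns `concentration` (uM) and `phi` (percent)
#' @export
simulateTitration <- function(truth) {
  validObject(truth)
  C <- truth@concentrations
  phi0 <- truth@phiMax * C / (C + truth@kd)
  eps <- withSeed(truth@seed, rnorm(length(C), 0, truth@noiseCv))
  data.frame(concentration = C, phi = phi0 * (1 + eps))
}

#' @rdname TitrationTruth-class
#' @param phiMax,kd,concentrations,noiseCv,seed see slots
#' @export
TitrationTruth <- function(phiMax = 12, kd = 1.2,
                           concentrations = exp(seq(log(0.02), log(4),
                                                    length.out = 8)),
                           noiseCv = 0.1, seed = 1L) {
  new("TitrationTruth", phiMax = phiMax, kd = kd,
      concentrations = concentrations, noiseCv = noiseCv,
      seed = as.integer(seed))
}

#' @rdname FrapTruth-class
#' @param mobileFraction,recoveryTau,acqBleachRate,prebleachLevel see slots
#' @param frameInterval,nFrames,noiseSd,seed see slots
#' @export
FrapTruth <- function(mobileFraction = 0.1, recoveryTau = 5,
                      acqBleachRate = 0.005, prebleachLevel = 1000,
                      frameInterval = 0.5, nFrames = 60L, noiseSd = 0,
                      seed = 1L) {
  new("FrapTruth", mobileFraction = mobileFraction, recoveryTau = recoveryTau,
      acqBleachRate = acqBleachRate, prebleachLevel = prebleachLevel,
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Simulate a FRAP experiment with acquisition photobleaching
#'
#' The bleached region starts fully bleached at frame 0 and recovers as
#' M(t) = mobileFraction * (1 - exp(-t/tau)); the reference region stays at
#' the pre-bleach level. Both regions are multiplied by the shared per-frame
#' acquisition-bleaching factor (1 - acqBleachRate)^frame, then Gaussian
#' noise is added.
#'
#' @param truth a [FrapTruth-class]
#' @return a [FrapTrace-class] (use [as.data.frame()] for the tabular form)
#' @export
simulateFrap <- function(truth) {
  validObject(truth)
  fr <- seq_len(truth@nFrames) - 1L
  t <- fr * truth@frameInterval
  recov <- truth@mobileFraction * (1 - exp(-t / truth@recoveryTau))
  bleachFac <- (1 - truth@acqBleachRate)^fr
  bl <- truth@prebleachLevel * recov * bleachFac
  rf <- truth@prebleachLevel * bleachFac
  withSeed(truth@seed, {
    bl <- bl + rnorm(length(t), 0, truth@noiseSd)
    rf <- rf + rnorm(length(t), 0, truth@noiseSd)
  })
  new("FrapTrace", times = t, bleached = bl, reference = rf,
      prebleachBleached = truth@prebleachLevel,
      prebleachReference = truth@prebleachLevel)
}

#' @describeIn FrapTrace tabular form (time, bleached, reference)
#' @param x a `FrapTrace`
#' @param row.names,optional,... passed on conventionally; unused
#' @export
as.data.frame.FrapTrace <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = x@times, bleached = x@bleached, reference = x@reference)
}

#' @rdname TetherTruth-class
#' @param gammaTrue,sigmaTest,nPairsPerArea,angleNoiseSd,seed see slots
#' @export
TetherTruth <- function(gammaTrue = 5e-6, sigmaTest = 0.05,
                        nPairsPerArea = 1000, angleNoiseSd = 0, seed = 1L) {
  new("TetherTruth", gammaTrue = gammaTrue, sigmaTest = sigmaTest,
      nPairsPerArea = nPairsPerArea, angleNoiseSd = angleNoiseSd,
      seed = as.integer(seed))
}

#' Simulate a tension series of GUV-GUV contact geometries
#'
#' For each test tension sigma_i the contact angle is
#' theta_i = arccos(1 - gamma/sigma_i) plus Gaussian angle noise. The
#' contact-zone protein intensity is generated to be consistent with the
#' bond density `nPairsPerArea` through the supplied calibration (ezrin dimer
#' convention: protein density = 2 x bond density).
#'
#' @param truth a [TetherTruth-class]
#' @param sigmas test tensions, mN/m
#' @param calibration a [SurfaceDensityCalibration-class] used to invert
#'   intensity from density; defaults to a unit calibration (A = 1,
#'   brightnessRatio = 1, labelingDegree = 1)
#' @return data.frame with columns `sigma` (mN/m), `theta` (rad),
#'   `protein_intensity` (a.u.)
#' @export
simulateTetherSeries <- function(truth, sigmas,
                                 calibration = surfaceDensityCalibration(A = 1)) {
  validObject(truth)
  if (any(sigmas <= 0)) stop("tensions must be > 0")
  sN <- mNm_to_Nm(sigmas)
  if (truth@gammaTrue >= min(sN))
    stop("impossible geometry: gammaTrue >= sigma gives cos(theta) <= 0")
  theta0 <- acos(1 - truth@gammaTrue / sN)
  theta <- withSeed(truth@seed,
                    theta0 + rnorm(length(sigmas), 0, truth@angleNoiseSd))
  theta <- pmin(pmax(theta, 0), pi / 2 - 1e-9)
  dens <- 2 * truth@nPairsPerArea     # molecules/um^2, dimers
  intensity <- dens * calibration@brightnessRatio * calibration@labelingDegree /
    calibration@A
  data.frame(sigma = sigmas, theta = theta,
             protein_intensity = rep(intensity, length(sigmas)))
}

#' Simulate nanotube assembly-class counts
#'
#' Multinomial draw of `nTubes` tubes over the assembly classes, reproducible
#' under `seed`.
#'
#' @param probabilities class probabilities, summing to 1
#' @param nTubes number of tubes observed (>= 0)
#' @param seed RNG seed
#' @return named integer vector of per-class counts
#' @export
simulateClassCounts <- function(probabilities, nTubes, seed = 1L) {
  if (nTubes < 0) stop("nTubes must be >= 0")
  if (abs(sum(probabilities) - 1) > 1e-8)
    stop("probabilities must sum to 1")
  if (is.null(names(probabilities)))
    names(probabilities) <- paste0("class", seq_along(probabilities))
  if (nTubes == 0) {
    out <- integer(length(probabilities))
  } else {
    out <- withSeed(seed, as.integer(rmultinom(1, nTubes, probabilities)))
  }
  names(out) <- names(probabilities)
  out
}
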