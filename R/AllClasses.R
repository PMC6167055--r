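## ---- synthetic-data ground-truth bundles ------------------------------------

#' Ground-truth parameters for a rendered confocal-like scene
#'
#' A `SyntheticScene` bundles everything needed to render a two-channel
#' (membrane dye, labeled protein) equatorial confocal section of a GUV,
#' optionally with a pulled membrane nanotube or a second, tethered GUV.
#' Rendering from a stated ground truth makes every downstream quantification
#' stage testable by parameter recovery.
#'
#' @slot sceneKind one of `"guv_with_tube"`, `"two_guv_contact"`, `"guv_only"`.
#' @slot guvRadius GUV radius in micrometres.
#' @slot tubeRatioMembrane ground-truth (Itube/Ivesicle) of the membrane dye,
#'   in (0, 1]; proportional to tube radius.
#' @slot sortingTrue ground-truth sorting ratio S (>= 0).
#' @slot proteinDensity protein surface density on the vesicle, molecules/um^2.
#' @slot psfSigma Gaussian PSF standard deviation in pixels (>= 0).
#' @slot backgroundLevel constant additive background, a.u.
#' @slot noiseSd additive Gaussian noise SD, a.u.
#' @slot gainMembrane,gainProtein channel gains, a.u. per unit density.
#' @slot pixelSize physical pixel size, micrometres per pixel.
#' @slot imageSize image side length in pixels (square frame).
#' @slot seed RNG seed; identical seed gives bit-identical output.
#' @export
setClass("SyntheticScene",
  representation(
    sceneKind = "character",
    guvRadius = "numeric",
    tubeRatioMembrane = "numeric",
    sortingTrue = "numeric",
    proteinDensity = "numeric",
    psfSigma = "numeric",
    backgroundLevel = "numeric",
    noiseSd = "numeric",
    gainMembrane = "numeric",
    gainProtein = "numeric",
    pixelSize = "numeric",
    imageSize = "integer",
    seed = "integer"
  ),
  prototype(
    sceneKind = "guv_with_tube", guvRadius = 4, tubeRatioMembrane = 0.4,
    sortingTrue = 1, proteinDensity = 500, psfSigma = 1,
    backgroundLevel = 100, noiseSd = 2, gainMembrane = 1, gainProtein = 1,
    pixelSize = 0.1, imageSize = 160L, seed = 1L
  )
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  if (!object@sceneKind %in% c("guv_with_tube", "two_guv_contact", "guv_only"))
    msg <- c(msg, "sceneKind must be guv_with_tube, two_guv_contact or guv_only")
  if (object@guvRadius <= 0) msg <- c(msg, "guvRadius must be > 0")
  if (object@tubeRatioMembrane <= 0 || object@tubeRatioMembrane > 1)
    msg <- c(msg, "tubeRatioMembrane must be in (0, 1]")
  if (object@sortingTrue < 0) msg <- c(msg, "sortingTrue must be >= 0")
  if (object@proteinDensity < 0) msg <- c(msg, "proteinDensity must be >= 0")
  if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@gainMembrane <= 0 || object@gainProtein <= 0)
    msg <- c(msg, "channel gains must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@imageSize < 32L) msg <- c(msg, "imageSize must be >= 32 px")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated binding titration
#'
#' Parameters of the hyperbolic (Langmuir) binding curve
#' Phi(C) = phiMax * C / (C + Kd) from which noisy titrations are drawn.
#'
#' @slot phiMax maximum membrane surface fraction, percent, in (0, 100].
#' @slot kd dissociation constant, micromolar (> 0).
#' @slot concentrations bulk concentrations, micromolar (>= 0).
#' @slot noiseCv multiplicative Gaussian noise coefficient of variation.
#' @slot seed RNG seed.
#' @export
setClass("TitrationTruth",
  representation(phiMax = "numeric", kd = "numeric", concentrations = "numeric",
                 noiseCv = "numeric", seed = "integer"),
  prototype(phiMax = 12, kd = 1.2,
            concentrations = exp(seq(log(0.02), log(4), length.out = 8)),
            noiseCv = 0.1, seed = 1L)
)

setValidity("TitrationTruth", function(object) {
  msg <- character()
  if (object@phiMax <= 0 || object@phiMax > 100)
    msg <- c(msg, "phiMax must be in (0, 100]")
  if (object@kd <= 0) msg <- c(msg, "kd must be > 0")
  if (length(object@concentrations) == 0)
    msg <- c(msg, "concentrations must be non-empty")
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated FRAP experiment
#'
#' Single-exponential recovery with plateau equal to the mobile fraction,
#' shared per-frame acquisition photobleaching on the bleached and reference
#' regions, and additive Gaussian noise.
#'
#' @slot mobileFraction fraction of fluorophores that recover, in [0, 1].
#' @slot recoveryTau recovery time constant, seconds.
#' @slot acqBleachRate per-frame acquisition bleaching fraction (>= 0).
#' @slot prebleachLevel pre-bleach intensity, a.u.
#' @slot frameInterval time between frames, seconds.
#' @slot nFrames number of post-bleach frames (>= 3).
#' @slot noiseSd additive Gaussian noise SD, a.u.
#' @slot seed RNG seed.
#' @export
setClass("FrapTruth",
  representation(mobileFraction = "numeric", recoveryTau = "numeric",
                 acqBleachRate = "numeric", prebleachLevel = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 noiseSd = "numeric", seed = "integer"),
  prototype(mobileFraction = 0.1, recoveryTau = 5, acqBleachRate = 0.005,
            prebleachLevel = 1000, frameInterval = 0.5, nFrames = 60L,
            noiseSd = 0, seed = 1L)
)

setValidity("FrapTruth", function(object) {
  msg <- character()
  if (object@mobileFraction < 0 || object@mobileFraction > 1)
    msg <- c(msg, "mobileFraction must be in [0, 1]")
  if (object@recoveryTau <= 0) msg <- c(msg, "recoveryTau must be > 0")
  if (object@acqBleachRate < 0 || object@acqBleachRate >= 1)
    msg <- c(msg, "acqBleachRate must be in [0, 1)")
  if (object@prebleachLevel <= 0) msg <- c(msg, "prebleachLevel must be > 0")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@nFrames < 3L) msg <- c(msg, "nFrames must be >= 3")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated GUV-GUV tethering series
#'
#' The contact angle follows the force balance sigma*cos(theta) = sigma -
#' gamma, so theta = arccos(1 - gamma/sigma); gammaTrue must be below every
#' test tension for the geometry to exist.
#'
#' @slot gammaTrue adhesion (tethering) energy per unit area, J/m^2 (>= 0).
#' @slot sigmaTest test-GUV membrane tension, mN/m (> 0).
#' @slot nPairsPerArea bond (e.g. ezrin dimer) density in the contact zone,
#'   per um^2 (> 0).
#' @slot angleNoiseSd Gaussian noise SD on the measured angle, radians.
#' @slot seed RNG seed.
#' @export
setClass("TetherTruth",
  representation(gammaTrue = "numeric", sigmaTest = "numeric",
                 nPairsPerArea = "numeric", angleNoiseSd = "numeric",
                 seed = "integer"),
  prototype(gammaTrue = 5e-6, sigmaTest = 0.05, nPairsPerArea = 1000,
            angleNoiseSd = 0, seed = 1L)
)

setValidity("TetherTruth", function(object) {
  msg <- character()
  if (object@gammaTrue < 0) msg <- c(msg, "gammaTrue must be >= 0")
  if (object@sigmaTest <= 0) msg <- c(msg, "sigmaTest must be > 0")
  if (object@gammaTrue >= mNm_to_Nm(object@sigmaTest))
    msg <- c(msg, "gammaTrue must be < sigmaTest (else cos(theta) leaves (0,1])")
  if (object@nPairsPerArea <= 0) msg <- c(msg, "nPairsPerArea must be > 0")
  if (object@angleNoiseSd < 0) msg <- c(msg, "angleNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---- image quantification ---------------------------------------------------

#' Regions of interest for profile extraction
#'
#' Both ROI flavours are defined by the two endpoints of the profile axis
#' (the direction along which the intensity profile runs, perpendicular to
#' the membrane or tube) and an averaging width perpendicular to that axis.
#' `RectRoi` is the rectangular ROI used for tube-pulling quantification
#' (background rule: first/last 15); `LineRoi` is the wide-line ROI used for
#' FRAP and tubulation assays (background rule: pooled first/last 10).
#'
#' @slot endpoints 2x2 numeric matrix, rows = (x, y) of start and end, px.
#' @slot width averaging extent perpendicular to the profile axis, px (>= 1).
#' @name Roi
#' @export
setClass("Roi", representation("VIRTUAL",
  endpoints = "matrix", width = "numeric"))

setValidity("Roi", function(object) {
  msg <- character()
  if (!is.numeric(object@endpoints) || !all(dim(object@endpoints) == c(2L, 2L)))
    msg <- c(msg, "endpoints must be a 2x2 numeric matrix (rows = points, cols = x,y)")
  if (object@width < 1) msg <- c(msg, "width must be >= 1 px")
  if (length(msg)) msg else TRUE
})

#' @rdname Roi
#' @export
setClass("RectRoi", contains = "Roi")

#' @rdname Roi
#' @export
setClass("LineRoi", contains = "Roi")

#' A one-dimensional averaged fluorescence profile
#'
#' One intensity value per position along the profile axis of an ROI; each
#' value is the mean across the ROI's averaging width. Raw material for the
#' background and peak rules.
#'
#' @slot positions positions along the profile axis, px.
#' @slot values mean intensities, a.u.
#' @slot channel source channel identifier.
#' @export
setClass("IntensityProfile",
  representation(positions = "numeric", values = "numeric", channel = "character"),
  prototype(positions = numeric(), values = numeric(), channel = "unknown")
)

setValidity("IntensityProfile", function(object) {
  if (length(object@positions) != length(object@values))
    "positions and values must have equal length" else TRUE
})

## ---- surface density --------------------------------------------------------

#' Fluorescence-to-surface-density calibration constants
#'
#' The chain converting a background-subtracted vesicle fluorescence
#' intensity to molecules per square micrometre and to a membrane surface
#' fraction: n_protein = A * I / (brightnessRatio * labelingDegree), and
#' Phi = n_protein * footprint.
#'
#' @slot A slope relating HPC* lipid-dye density (molecules/um^2) to vesicle
#'   intensity (a.u.); session-specific, never defaulted.
#' @slot brightnessRatio intensity ratio I_AX488 / I_HPC* at equal bulk
#'   concentration under identical acquisition.
#' @slot labelingDegree dyes per protein (n*).
#' @slot footprint membrane area of one protein, nm^2 (ezrin ~20, I-BAR ~50).
#' @slot lipidArea area per lipid, nm^2 (0.7 by convention).
#' @export
setClass("SurfaceDensityCalibration",
  representation(A = "numeric", brightnessRatio = "numeric",
                 labelingDegree = "numeric", footprint = "numeric",
                 lipidArea = "numeric"),
  prototype(A = NA_real_, brightnessRatio = 1, labelingDegree = 1,
            footprint = 20, lipidArea = 0.7)
)

setValidity("SurfaceDensityCalibration", function(object) {
  msg <- character()
  for (s in c("A", "brightnessRatio", "labelingDegree", "footprint", "lipidArea")) {
    v <- slot(object, s)
    if (!is.na(v) && v <= 0) msg <- c(msg, sprintf("%s must be > 0", s))
  }
  if (length(msg)) msg else TRUE
})

## ---- curvature sorting ------------------------------------------------------

#' Paired tube/vesicle intensities for one sorting measurement
#'
#' Background-subtracted intensities of the protein and membrane-dye
#' channels on the nanotube and on the vesicle, with the vesicle coverage
#' and the below-detection flag that forces S = 0.
#'
#' @slot iTubeProtein,iVesProtein,iTubeMembrane,iVesMembrane
#'   background-subtracted intensities, a.u.
#' @slot phiV vesicle protein surface fraction, percent.
#' @slot belowDetection TRUE when the tube protein signal is at noise level;
#'   the sorting ratio is then defined as 0.
#' @export
setClass("SortingMeasurement",
  representation(iTubeProtein = "numeric", iVesProtein = "numeric",
                 iTubeMembrane = "numeric", iVesMembrane = "numeric",
                 phiV = "numeric", belowDetection = "logical"),
  prototype(phiV = NA_real_, belowDetection = FALSE)
)

setValidity("SortingMeasurement", function(object) {
  msg <- character()
  if (object@iVesProtein <= 0 || object@iVesMembrane <= 0)
    msg <- c(msg, "vesicle intensities must be > 0")
  if (object@iTubeProtein < 0 || object@iTubeMembrane < 0)
    msg <- c(msg, "tube intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---- tethering --------------------------------------------------------------

#' Geometry and fluorescence of one GUV-GUV tethering measurement
#'
#' @slot sigmaTest test-GUV tension, mN/m (the reference GUV is held at high
#'   tension, > 0.4 mN/m, recorded as metadata).
#' @slot theta contact angle, radians, in [0, pi/2).
#' @slot contactArea contact-zone area, um^2.
#' @slot proteinIntensity background-subtracted protein intensity in the
#'   contact zone (mean over the zone ROI), a.u.
#' @slot referenceTension reference-GUV tension, mN/m (metadata).
#' @slot calibration a [SurfaceDensityCalibration] for converting intensity
#'   to molecular density.
#' @export
setClass("TetherGeometry",
  representation(sigmaTest = "numeric", theta = "numeric",
                 contactArea = "numeric", proteinIntensity = "numeric",
                 referenceTension = "numeric",
                 calibration = "SurfaceDensityCalibration"),
  prototype(referenceTension = 0.5)
)

setValidity("TetherGeometry", function(object) {
  msg <- character()
  if (object@sigmaTest <= 0) msg <- c(msg, "sigmaTest must be > 0")
  if (object@theta < 0 || object@theta >= pi / 2)
    msg <- c(msg, "theta must be in [0, pi/2)")
  if (object@contactArea <= 0) msg <- c(msg, "contactArea must be > 0")
  if (object@proteinIntensity < 0) msg <- c(msg, "proteinIntensity must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---- FRAP -------------------------------------------------------------------

#' A FRAP time series with its photobleaching reference
#'
#' Bleached-region and reference-region intensities are background-subtracted
#' (wide-line rule) peak intensities; `prebleachBleached` and
#' `prebleachReference` are the corresponding pre-bleach values used for
#' normalisation.
#'
#' @slot times acquisition times, seconds (frame 0 = first post-bleach frame).
#' @slot bleached bleached-region intensities, a.u.
#' @slot reference reference-region intensities, a.u.
#' @slot prebleachBleached,prebleachReference pre-bleach intensities, a.u.
#' @export
setClass("FrapTrace",
  representation(times = "numeric", bleached = "numeric", reference = "numeric",
                 prebleachBleached = "numeric", prebleachReference = "numeric")
)

setValidity("FrapTrace", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@bleached) != n || length(object@reference) != n)
    msg <- c(msg, "times, bleached and reference must have equal length")
  if (object@prebleachBleached <= 0 || object@prebleachReference <= 0)
    msg <- c(msg, "prebleach intensities must be > 0")
  if (length(msg)) msg else TRUE
})

## ---- binding ----------------------------------------------------------------

#' Result of a hyperbolic (Langmuir) binding fit
#'
#' @slot phiMax fitted (or fixed) maximum surface fraction, percent.
#' @slot kd fitted dissociation constant, micromolar.
#' @slot phiMaxFixed TRUE when phiMax was held fixed.
#' @slot covariance covariance matrix of the free parameter estimates.
#' @slot residuals fit residuals (percent).
#' @slot data the fitted table (columns `concentration`, `phi`).
#' @export
setClass("BindingFit",
  representation(phiMax = "numeric", kd = "numeric", phiMaxFixed = "logical",
                 covariance = "matrix", residuals = "numeric",
                 data = "data.frame")
)

setValidity("BindingFit", function(object) {
  msg <- character()
  if (object@kd <= 0) msg <- c(msg, "kd must be > 0")
  if (object@phiMax <= 0) msg <- c(msg, "phiMax must be > 0")
  if (length(msg)) msg else TRUE
})

## ---- assembly statistics ----------------------------------------------------

#' Counts of categorical outcomes per experimental group
#'
#' Rows are groups (e.g. ezrinTD, ezrinWT), columns are classes (disordered,
#' stacked, isolated, ...).
#'
#' @slot counts non-negative integer matrix, groups x classes, with dimnames.
#' @export
setClass("ClassCounts", representation(counts = "matrix"))

setValidity("ClassCounts", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "counts must be numeric")
  else {
    if (any(m < 0) || any(m != round(m)))
      msg <- c(msg, "counts must be non-negative integers")
    if (any(rowSums(m) <= 0)) msg <- c(msg, "group totals must be > 0")
  }
  if (length(msg)) msg else TRUE
})
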