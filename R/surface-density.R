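#' @include AllClasses.R
NULL

#' @rdname SurfaceDensityCalibration-class
#' @param A,brightnessRatio,labelingDegree,footprint,lipidArea see slots.
#'   `A` is session-specific (it depends on the illumination setting) and has
#'   no default: it must be measured per dataset with [fitHpcCalibration()].
#' @export
surfaceDensityCalibration <- function(A, brightnessRatio = 1,
                                      labelingDegree = 1, footprint = 20,
                                      lipidArea = 0.7) {
  if (missing(A)) stop("'A' has no default: fit it per session with fitHpcCalibration()")
  new("SurfaceDensityCalibration", A = A, brightnessRatio = brightnessRatio,
      labelingDegree = labelingDegree, footprint = footprint,
      lipidArea = lipidArea)
}

setMethod("show", "SurfaceDensityCalibration", function(object) {
  cat("SurfaceDensityCalibration\n",
      sprintf("  A = %.4g (molecules/um^2)/a.u., I_AX488/I_HPC* = %.3g, n* = %.3g\n",
              object@A, object@brightnessRatio, object@labelingDegree),
      sprintf("  footprint = %.3g nm^2, lipid area = %.3g nm^2\n",
              object@footprint, object@lipidArea))
})

#' Fit the HPC* lipid-dye calibration slope A
#'
#' Least-squares slope through the origin of HPC* surface density
#' (molecules/um^2) against vesicle intensity (a.u.): n_HPC* = A x I. The
#' zero intercept follows from the proportionality of dye density and
#' fluorescence; a free-intercept diagnostic fit is available behind
#' `throughOrigin = FALSE`. Reference densities span 0.04-0.16 mole% HPC* in
#' DOPC, i.e. 1120-4480 molecules/um^2 at 0.7 nm^2 per lipid.
#'
#' @param hpcDensity HPC* densities, molecules/um^2
#' @param vesicleIntensity background-subtracted vesicle intensities, a.u.
#' @param throughOrigin fit through the origin (default TRUE)
#' @return list with `A` (slope), `sd` (slope SD) and `residuals`
#' @export
fitHpcCalibration <- function(hpcDensity, vesicleIntensity,
                              throughOrigin = TRUE) {
  if (length(hpcDensity) < 2 || length(hpcDensity) != length(vesicleIntensity))
    stop("need >= 2 (density, intensity) pairs of equal length")
  if (all(vesicleIntensity == 0)) stop("all intensities are zero")
  if (any(hpcDensity <= 0) || any(vesicleIntensity < 0))
    stop("densities must be > 0 and intensities >= 0")
  if (throughOrigin) {
    fit <- stats::lm(hpcDensity ~ 0 + vesicleIntensity)
    A <- unname(stats::coef(fit)[1])
    sdA <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[1]))
  } else {
    fit <- stats::lm(hpcDensity ~ vesicleIntensity)
    A <- unname(stats::coef(fit)[2])
    sdA <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  }
  if (!is.finite(sdA)) sdA <- 0       # exact fit: zero residual variance
  list(A = A, sd = sdA, residuals = unname(stats::residuals(fit)))
}

#' Convert HPC* mole fraction to surface density
#'
#' Both-leaflet convention: density = 2 x moleFraction / lipidArea, matching
#' the stated 0.04 mole% <-> 1120 molecules/um^2 equivalence (0.0004 x 2 /
#' 0.7 nm^2 = 1142/um^2 ~ 1120; the published figures are used as-is when
#' given).
#'
#' @param moleFraction HPC* mole fraction (not percent)
#' @param lipidArea area per lipid, nm^2
#' @return molecules per um^2
#' @export
hpcMoleFractionToDensity <- function(moleFraction, lipidArea = 0.7) {
  2 * moleFraction / (lipidArea * 1e-6)   # nm^2 -> um^2
}

#' Protein surface density from vesicle fluorescence
#'
#' n_protein = A x I / (brightnessRatio x labelingDegree): the HPC*-equivalent
#' density scaled by the dye brightness ratio and the protein's degree of
#' labeling.
#'
#' @param intensity background-subtracted protein vesicle intensity, a.u.
#' @param calibration a [SurfaceDensityCalibration-class]
#' @return molecules per um^2
#' @export
proteinDensity <- function(intensity, calibration) {
  if (any(intensity < 0)) stop("intensity must be >= 0")
  if (is.na(calibration@A)) stop("calibration constant A is not set")
  calibration@A * intensity /
    (calibration@brightnessRatio * calibration@labelingDegree)
}

#' Membrane surface fraction from protein density
#'
#' Phi = density x footprint, with density in molecules/um^2 and footprint in
#' nm^2 (1 um^2 = 1e6 nm^2), returned as percent. Values above 100% are
#' nonphysical and flagged with a warning.
#'
#' @param density molecules per um^2
#' @param footprint protein footprint, nm^2 (ezrin ~20, I-BAR domain ~50)
#' @return surface fraction, percent
#' @export
surfaceFraction <- function(density, footprint = 20) {
  if (any(density < 0) || footprint <= 0)
    stop("density must be >= 0 and footprint > 0")
  phi <- density * footprint * 1e-6 * 100
  if (any(phi > 100))
    warning("surface fraction exceeds 100%: nonphysical density/footprint combination")
  phi
}

#' @rdname surfaceFraction
#' @param phi surface fraction, percent
#' @return `densityFromFraction`: molecules per um^2
#' @export
densityFromFraction <- function(phi, footprint = 20) {
  phi / 100 / (footprint * 1e-6)
}
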