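#' @include AllClasses.R AllGenerics.R surface-density.R
NULL

#' @rdname TetherGeometry-class
#' @param sigmaTest test-GUV tension, mN/m
#' @param theta contact angle, radians
#' @param contactArea contact-zone area, um^2
#' @param proteinIntensity mean background-subtracted protein intensity in
#'   the contact zone, a.u.
#' @param calibration a [SurfaceDensityCalibration-class]
#' @param referenceTension reference-GUV tension, mN/m (should exceed
#'   0.4 mN/m so the reference GUV stays spherical; warned otherwise)
#' @export
tetherGeometry <- function(sigmaTest, theta, contactArea, proteinIntensity,
                           calibration, referenceTension = 0.5) {
  if (referenceTension <= 0.4)
    warning("reference-GUV tension <= 0.4 mN/m: reference vesicle may deviate from spherical")
  new("TetherGeometry", sigmaTest = sigmaTest, theta = theta,
      contactArea = contactArea, proteinIntensity = proteinIntensity,
      referenceTension = referenceTension, calibration = calibration)
}

setMethod("show", "TetherGeometry", function(object) {
  cat("TetherGeometry\n",
      sprintf("  sigma = %.3g mN/m, theta = %.3g rad, zone area = %.3g um^2\n",
              object@sigmaTest, object@theta, object@contactArea),
      sprintf("  gamma = %.3g J/m^2\n",
              gammaFromAngle(object@sigmaTest, object@theta)))
})

#' Adhesion energy from the contact-angle force balance
#'
#' At a GUV-GUV contact the tensions balance as sigma * cos(theta) = sigma -
#' gamma, so the tethering (adhesion) energy per unit area is
#' gamma = sigma * (1 - cos(theta)). Increasing in theta; zero at theta = 0.
#'
#' @param sigma test-GUV membrane tension, mN/m
#' @param theta contact angle, radians, in [0, pi/2)
#' @return gamma in J/m^2
#' @export
gammaFromAngle <- function(sigma, theta) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(theta < 0) || any(theta >= pi / 2))
    stop("theta out of range [0, pi/2)")
  mNm_to_Nm(sigma) * (1 - cos(theta))
}

#' Energy per molecular bond from adhesion energy and bond density
#'
#' Divides the areal tethering energy by the areal bond density and converts
#' to kBT (kBT = 4.11e-21 J at 25 C). For ezrin, bonds are dimers: bond
#' density = protein density / 2; for biotin-streptavidin, bond density =
#' streptavidin density. `efficiency` scales the fraction of zone protein
#' assumed to contribute (default 1: all of it).
#'
#' @param gamma adhesion energy, J/m^2
#' @param bondDensity bonds per um^2
#' @param efficiency fraction of bonds contributing, in (0, 1]
#' @return energy per bond, kBT
#' @export
energyPerBond <- function(gamma, bondDensity, efficiency = 1) {
  if (any(bondDensity <= 0)) stop("bond density must be > 0")
  if (efficiency <= 0 || efficiency > 1) stop("efficiency must be in (0, 1]")
  joules_to_kBT(areal_energy_per_molecule(gamma, bondDensity * efficiency))
}

#' Per-bond tethering energy of one measured contact
#'
#' Full chain for one [TetherGeometry-class]: gamma from the force balance,
#' protein density in the zone from the fluorescence calibration, bond
#' density from the dimer convention, then energy per bond in kBT.
#'
#' @param object a [TetherGeometry-class]
#' @param dimer TRUE for dimeric bonds (ezrin: bond density = protein
#'   density / 2); FALSE when the labelled species is the bond itself
#'   (streptavidin)
#' @param efficiency fraction of zone protein contributing (default 1)
#' @param ... unused
#' @return list: `gamma` (J/m^2), `proteinDensity` and `bondDensity`
#'   (per um^2), `energyPerBond_kBT`, `nBondsZone`
#' @export
setMethod("bondEnergy", "TetherGeometry",
          function(object, dimer = TRUE, efficiency = 1, ...) {
  g <- gammaFromAngle(object@sigmaTest, object@theta)
  dens <- proteinDensity(object@proteinIntensity, object@calibration)
  bondDens <- if (dimer) dens / 2 else dens
  list(gamma = g, proteinDensity = dens, bondDensity = bondDens,
       energyPerBond_kBT = energyPerBond(g, bondDens, efficiency),
       nBondsZone = bondDens * object@contactArea)
})

#' Summarise a tension series of tethering energies
#'
#' Groups (sigma, gamma, E_per_bond) records by tension and reports per-group
#' medians and IQRs plus a Spearman rank statistic for the gamma-versus-sigma
#' trend (the tension dependence of the apparent bond energy).
#'
#' @param sigma test tensions, mN/m
#' @param gamma adhesion energies, J/m^2
#' @param energyPerBond per-bond energies, kBT
#' @param digits tension rounding used to form groups (default 3)
#' @return list: `table` (per-tension medians/IQRs) and `trend` (Spearman rho
#'   of gamma vs sigma; 0 when either variable is constant)
#' @export
tensionSeriesSummary <- function(sigma, gamma, energyPerBond, digits = 3) {
  n <- length(sigma)
  if (n < 1) stop("need at least one record")
  stopifnot(length(gamma) == n, length(energyPerBond) == n)
  grp <- factor(round(sigma, digits))
  tab <- do.call(rbind, lapply(levels(grp), function(g) {
    i <- grp == g
    data.frame(sigma = as.numeric(g), n = sum(i),
               medianGamma = stats::median(gamma[i]),
               iqrGamma = stats::IQR(gamma[i]),
               medianEnergy = stats::median(energyPerBond[i]),
               iqrEnergy = stats::IQR(energyPerBond[i]))
  }))
  rho <- if (n < 2 || stats::sd(sigma) == 0 || stats::sd(gamma) == 0) 0
         else suppressWarnings(stats::cor(sigma, gamma, method = "spearman"))
  list(table = tab, trend = rho)
}

#' Contact angle from clicked contour points by circle fitting
#'
#' Helper replacing manual angle reading: given points clicked along the test
#' GUV's contour near the contact and the two contact-line endpoints, fits a
#' least-squares circle (Kasa fit) to the contour and returns the angle at
#' the contact line between the membrane tangent and the contact plane.
#'
#' @param contour n x 2 matrix of (x, y) contour points, n >= 3
#' @param contactLine 2 x 2 matrix, the two contact-line endpoints
#' @return contact angle theta, radians
#' @export
contactAngleFromPoints <- function(contour, contactLine) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop("need >= 3 contour points to fit a circle")
  x <- contour[, 1]; y <- contour[, 2]
  # Kasa algebraic circle fit: minimise ||x^2+y^2 - 2ax - 2by - c||
  M <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(M, x^2 + y^2)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  cl <- as.matrix(contactLine)
  mid <- colMeans(cl)
  chord <- cl[2, ] - cl[1, ]
  d <- sqrt(sum((mid - c(cx, cy))^2))   # centre-to-chord distance
  half <- sqrt(sum(chord^2)) / 2
  if (half > r) stop("contact line wider than fitted circle: inconsistent points")
  # angle between membrane tangent at the contact line and the contact plane
  acos(pmin(1, d / r))
}
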