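#' @include AllClasses.R AllGenerics.R image-quant.R
NULL

#' @rdname SortingMeasurement-class
#' @param iTubeProtein,iVesProtein,iTubeMembrane,iVesMembrane
#'   background-subtracted intensities, a.u.
#' @param phiV vesicle protein surface fraction, percent (optional)
#' @param belowDetection TRUE when the tube protein signal is at noise level
#' @export
sortingMeasurement <- function(iTubeProtein, iVesProtein, iTubeMembrane,
                               iVesMembrane, phiV = NA_real_,
                               belowDetection = FALSE) {
  new("SortingMeasurement", iTubeProtein = iTubeProtein,
      iVesProtein = iVesProtein, iTubeMembrane = iTubeMembrane,
      iVesMembrane = iVesMembrane, phiV = phiV,
      belowDetection = belowDetection)
}

setMethod("show", "SortingMeasurement", function(object) {
  cat("SortingMeasurement\n",
      sprintf("  protein tube/vesicle = %.3g/%.3g, membrane tube/vesicle = %.3g/%.3g\n",
              object@iTubeProtein, object@iVesProtein,
              object@iTubeMembrane, object@iVesMembrane),
      sprintf("  phiV = %.3g%%, below detection: %s, S = %.3g\n",
              object@phiV, object@belowDetection, sortingRatio(object)))
})

#' Curvature sorting ratio S
#'
#' S = (Itube/Ivesicle)_protein / (Itube/Ivesicle)_membrane, the tube
#' enrichment of the protein normalized by the membrane dye (which reports
#' tube geometry). S > 1 means curvature-driven enrichment; when the tube
#' protein signal is below detection the sorting ratio is defined as 0.
#'
#' @param m a [SortingMeasurement-class]
#' @param ... unused
#' @return dimensionless sorting ratio
#' @export
setMethod("sortingRatio", "SortingMeasurement", function(m, ...) {
  if (m@belowDetection) return(0)
  if (m@iTubeMembrane <= 0)
    stop("membrane tube intensity must be > 0 for a detected measurement")
  (m@iTubeProtein / m@iVesProtein) / (m@iTubeMembrane / m@iVesMembrane)
})

#' Quantify a rendered scene into a sorting measurement
#'
#' Runs the full image pipeline on a [RenderedScene-class]: extracts tube and
#' vesicle profiles in both channels with [sceneRois()] (or user ROIs),
#' applies the rectangular-ROI background rules (protein: first/last-15
#' average; membrane: first-15 top rule), and assembles a
#' [SortingMeasurement-class] with the below-detection flag from the protein
#' tube profile.
#'
#' @param rendered a [RenderedScene-class]
#' @param rois optional list with `tube` and `vesicle` ROIs; defaults to
#'   [sceneRois()]
#' @param detectionFactor below-detection threshold in robust noise SDs
#' @return a [SortingMeasurement-class]
#' @export
measureSceneSorting <- function(rendered, rois = sceneRois(rendered),
                                detectionFactor = 2) {
  mem <- rendered@membrane
  prot <- rendered@protein
  if (is.null(rois$tube))
    stop("no tube ROI: scene kind '", rendered@scene@sceneKind,
         "' has no tube to quantify")
  pTubeProt <- extractProfile(prot, rois$tube, channel = "protein")
  pVesProt <- extractProfile(prot, rois$vesicle, channel = "protein")
  pTubeMem <- extractProfile(mem, rois$tube, channel = "membrane")
  pVesMem <- extractProfile(mem, rois$vesicle, channel = "membrane")
  iTubeProt <- peakMinusBackground(pTubeProt, "rect",
                                   detectionFactor = detectionFactor)
  iVesProt <- peakMinusBackground(pVesProt, "rect",
                                  detectionFactor = detectionFactor)
  iTubeMem <- peakMinusBackground(pTubeMem, "top",
                                  detectionFactor = detectionFactor)
  iVesMem <- peakMinusBackground(pVesMem, "top",
                                 detectionFactor = detectionFactor)
  sortingMeasurement(
    iTubeProtein = max(as.numeric(iTubeProt), 0),
    iVesProtein = as.numeric(iVesProt),
    iTubeMembrane = as.numeric(iTubeMem),
    iVesMembrane = as.numeric(iVesMem),
    belowDetection = isTRUE(attr(iTubeProt, "belowDetection")))
}

#' Background-subtracted vesicle intensity of one channel of a rendered scene
#'
#' Convenience wrapper used in calibration workflows (e.g. measuring HPC*-like
#' reference GUVs rendered at known dye densities under the same optics):
#' extracts the vesicle profile and applies the stated background rule.
#'
#' @param rendered a [RenderedScene-class]
#' @param channel `"membrane"` or `"protein"`
#' @param rule background rule (default `"top"`: the membrane-dye convention)
#' @param rois optional ROI list; defaults to [sceneRois()]
#' @return background-subtracted peak intensity, a.u. (with `belowDetection`
#'   attribute)
#' @export
measureVesicleIntensity <- function(rendered, channel = "protein",
                                    rule = "rect", rois = sceneRois(rendered)) {
  img <- channelImage(rendered, channel)
  peakMinusBackground(extractProfile(img, rois$vesicle, channel = channel),
                      rule = rule)
}

#' Tube radius estimators
#'
#' Three routes to the nanotube radius:
#' \describe{
#'   \item{`radiusFromTension`}{mechanical equilibrium of a bare tube,
#'     R = sqrt(kappa / (2 sigma)).}
#'   \item{`radiusFromForce`}{from the tube-holding force, R = f / (4 pi
#'     sigma).}
#'   \item{`radiusFromFluorescence`}{from the membrane-dye tube/vesicle
#'     ratio, R = Rc x ratio, with Rc the dye-specific calibration slope
#'     (BODIPY TR: 200 +/- 50 nm; GM1*: 312 +/- 15 nm).}
#' }
#' The three agree exactly on self-consistently generated data.
#'
#' @param kappa bending rigidity, J (use `kappa_kBT * kBT_J` for kBT units)
#' @param sigma membrane tension, N/m
#' @param f tube-holding force, N
#' @param ratio membrane-dye (Itube/Ivesicle)
#' @param Rc fluorescence calibration slope, nm
#' @param RcSd optional SD of Rc for uncertainty propagation
#' @return radius in nm (`radiusFromFluorescence` attaches an `sd` attribute
#'   when `RcSd` is given)
#' @export
radiusFromTension <- function(kappa, sigma) {
  stopifnot_scalar(kappa, "kappa", positive = TRUE)
  if (any(sigma <= 0)) stop("sigma must be > 0")
  sqrt(kappa / (2 * sigma)) * 1e9
}

#' @rdname radiusFromTension
#' @export
radiusFromForce <- function(f, sigma) {
  if (any(f <= 0)) stop("force must be > 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  f / (4 * pi * sigma) * 1e9
}

#' @rdname radiusFromTension
#' @export
radiusFromFluorescence <- function(ratio, Rc = 200, RcSd = NULL) {
  if (any(ratio <= 0)) stop("ratio must be > 0")
  if (Rc <= 0) stop("Rc must be > 0")
  out <- Rc * ratio
  if (!is.null(RcSd)) attr(out, "sd") <- RcSd * ratio
  out
}

#' Fit the fluorescence-radius calibration slope Rc
#'
#' Zero-intercept least squares of reference radii (nm, e.g. from the force
#' route) on membrane-dye tube/vesicle ratios: R = Rc x ratio. Returns the
#' slope and its SD.
#'
#' @param ratio membrane-dye (Itube/Ivesicle) values
#' @param radius reference radii, nm
#' @return list with `Rc` (nm), `sd` (nm) and `residuals`
#' @export
fitRc <- function(ratio, radius) {
  if (length(ratio) < 2 || length(ratio) != length(radius))
    stop("need >= 2 (ratio, radius) pairs of equal length")
  if (all(ratio == 0)) stop("degenerate calibration: all ratios are zero")
  fit <- stats::lm(radius ~ 0 + ratio)
  sdRc <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[1]))
  if (!is.finite(sdRc)) sdRc <- 0   # exact collinear data: zero residual df
  list(Rc = unname(stats::coef(fit)[1]), sd = sdRc,
       residuals = unname(stats::residuals(fit)))
}

#' Group sorting measurements by vesicle coverage
#'
#' Assigns each measurement to a half-open coverage bin [lo, hi) and
#' summarises S per bin. Mean, SD, min and max are computed excluding S = 0
#' (below-detection) values, which are reported separately as a count — the
#' convention used for sorting-versus-radius panels. Coverage outside every
#' bin goes to an `"unbinned"` group.
#'
#' @param phiV vesicle coverages, percent
#' @param S sorting ratios (0 = below detection)
#' @param binEdges increasing bin edges, percent (default `c(0, 2, 5, Inf)`,
#'   i.e. the <2%, 2-5% and >5% coverage classes)
#' @return data.frame with one row per bin: n, nBelowDetection, meanS, sdS,
#'   minS, maxS (dispersion columns NA when no detected S in the bin)
#' @export
binByCoverage <- function(phiV, S, binEdges = c(0, 2, 5, Inf)) {
  if (is.unsorted(binEdges, strictly = TRUE)) stop("bin edges must be increasing")
  if (length(phiV) != length(S)) stop("phiV and S must have equal length")
  labs <- paste0("[", utils::head(binEdges, -1), ",",
                 utils::tail(binEdges, -1), ")")
  idx <- findInterval(phiV, binEdges, rightmost.closed = FALSE)
  grp <- ifelse(idx >= 1 & idx < length(binEdges), labs[idx], "unbinned")
  groups <- c(labs[labs %in% grp], if (any(grp == "unbinned")) "unbinned")
  out <- do.call(rbind, lapply(groups, function(g) {
    s <- S[grp == g]
    det <- s[s > 0]
    data.frame(bin = g, n = length(s), nBelowDetection = sum(s == 0),
               meanS = if (length(det)) mean(det) else NA_real_,
               sdS = if (length(det) > 1) stats::sd(det) else NA_real_,
               minS = if (length(det)) min(det) else NA_real_,
               maxS = if (length(det)) max(det) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Optional I-BAR tubulation ratio-to-radius anchor
#'
#' For inward-tubulation assays with no optical-tweezer calibration, radii
#' can only be anchored approximately: a membrane ratio of 0.4 corresponds to
#' a tubule radius of about 30 nm (and 0.3 to about 20 nm) by comparison
#' with published tether calibrations. This affine-through-origin conversion
#' (75 nm per unit ratio) is deliberately NOT a default anywhere; it is
#' provided only as an explicitly-invoked, clearly-tagged approximation.
#'
#' @param ratio membrane-dye (Itube/Ivesicle)
#' @return approximate radius, nm, with attribute `provenance`
#' @export
ibarRatioToRadius <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be > 0")
  structure(75 * ratio,
            provenance = "approximate anchor (ratio 0.4 ~ 30 nm); not a calibrated fit")
}
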