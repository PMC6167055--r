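#' @include AllClasses.R
NULL

setMethod("show", "BindingFit", function(object) {
  cat("BindingFit (hyperbolic / Langmuir isotherm)\n",
      sprintf("  phiMax = %.4g%% %s, Kd = %.4g uM\n", object@phiMax,
              if (object@phiMaxFixed) "(fixed)" else "(fitted)", object@kd),
      sprintf("  n = %d points, residual SD = %.3g\n",
              nrow(object@data), stats::sd(object@residuals)))
})

.langmuir <- function(C, phiMax, kd) phiMax * C / (C + kd)

#' Fit the hyperbolic (Langmuir) binding isotherm
#'
#' Nonlinear least squares of Phi(C) = phiMax * C / (C + Kd) to a titration
#' table. With `fixPhiMax` given, only Kd is free (the convention used when a
#' common saturation coverage is assumed across constructs); otherwise both
#' parameters are fitted jointly. Kd is bounded in (1e-4, 1e4) uM and phiMax
#' in (0, 100]; three log-spaced Kd starting values guard against local
#' minima. Unweighted least squares by default; `weights` (e.g. 1/SD^2 of
#' replicates) are accepted.
#'
#' @param data data.frame with columns `concentration` (uM) and `phi`
#'   (percent), as from [simulateTitration()]
#' @param fixPhiMax optional fixed phiMax, percent
#' @param weights optional least-squares weights
#' @return a [BindingFit-class]
#' @export
fitLangmuir <- function(data, fixPhiMax = NULL, weights = NULL) {
  stopifnot(all(c("concentration", "phi") %in% names(data)))
  C <- data$concentration
  phi <- data$phi
  if (length(C) < 3 || length(unique(C)) < 2)
    stop("insufficient support: need >= 3 titration points at >= 2 concentrations")
  kdGuess <- stats::median(C[C > 0])
  if (!(any(C < kdGuess) && any(C > kdGuess)))
    warning("concentrations may not span the apparent Kd; fit can be poorly constrained")
  if (is.null(weights)) weights <- rep(1, length(C))
  df <- data.frame(C = C, phi = phi)
  kdStarts <- kdGuess * c(0.1, 1, 10)

  tryFit <- function(start, formula, lower, upper) {
    tryCatch(
      stats::nls(formula, data = df, start = start, weights = weights,
                 algorithm = "port", lower = lower, upper = upper,
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
  }

  if (!is.null(fixPhiMax)) {
    stopifnot_scalar(fixPhiMax, "fixPhiMax", positive = TRUE)
    phiMaxFixed <- TRUE
    fits <- lapply(kdStarts, function(k0)
      tryFit(list(kd = k0), phi ~ fixPhiMax * C / (C + kd),
             lower = c(kd = 1e-4), upper = c(kd = 1e4)))
  } else {
    phiMaxFixed <- FALSE
    fits <- lapply(kdStarts, function(k0)
      tryFit(list(phiMax = max(phi), kd = k0),
             phi ~ phiMax * C / (C + kd),
             lower = c(phiMax = 1e-6, kd = 1e-4),
             upper = c(phiMax = 100, kd = 1e4)))
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("Langmuir fit did not converge from any starting value")
  rss <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  kd <- unname(cf[["kd"]])
  phiMax <- if (phiMaxFixed) fixPhiMax else unname(cf[["phiMax"]])
  vc <- tryCatch(stats::vcov(best), error = function(e)
    matrix(NA_real_, length(cf), length(cf), dimnames = list(names(cf), names(cf))))
  new("BindingFit", phiMax = phiMax, kd = kd, phiMaxFixed = phiMaxFixed,
      covariance = vc, residuals = unname(stats::residuals(best)),
      data = data.frame(concentration = C, phi = phi))
}

#' Predict surface fraction from a binding fit
#'
#' Evaluates the fitted hyperbola at bulk concentration `C`; monotone in C
#' and bounded by phiMax.
#'
#' @param fit a [BindingFit-class]
#' @param C bulk concentrations, uM (>= 0)
#' @return predicted surface fraction, percent
#' @export
predictPhi <- function(fit, C) {
  if (any(C < 0)) stop("concentrations must be >= 0")
  .langmuir(C, fit@phiMax, fit@kd)
}

#' Median intensity above a threshold (flow-cytometry summary)
#'
#' The per-sample intensity summary used for vesicle populations in flow
#' cytometry: the median of the intensity distribution strictly above the
#' gating threshold. When no event passes the gate the result is `NA` with
#' attribute `belowDetection = TRUE`.
#'
#' @param intensities event intensities, a.u.
#' @param threshold gating threshold, a.u.
#' @return median intensity above threshold (a.u.), with `belowDetection`
#'   attribute
#' @export
cytometryMedian <- function(intensities, threshold) {
  if (!length(intensities)) stop("empty intensity vector")
  if (!is.finite(threshold)) stop("threshold must be finite")
  keep <- intensities[intensities > threshold]
  if (!length(keep))
    return(structure(NA_real_, belowDetection = TRUE))
  structure(stats::median(keep), belowDetection = FALSE)
}
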