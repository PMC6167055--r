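#' @include AllClasses.R
NULL

#' @rdname FrapTrace-class
#' @param times,bleached,reference see slots
#' @param prebleachBleached,prebleachReference pre-bleach intensities; the
#'   reference value defaults to the bleached-region value (same laser and
#'   acquisition settings)
#' @export
frapTrace <- function(times, bleached, reference, prebleachBleached,
                      prebleachReference = prebleachBleached) {
  new("FrapTrace", times = as.numeric(times), bleached = as.numeric(bleached),
      reference = as.numeric(reference),
      prebleachBleached = prebleachBleached,
      prebleachReference = prebleachReference)
}

setMethod("show", "FrapTrace", function(object) {
  cat(sprintf("FrapTrace: %d frames over %.3g s, prebleach %.3g a.u.\n",
              length(object@times), max(object@times),
              object@prebleachBleached))
})

#' Photobleaching correction and pre-bleach normalization of a FRAP trace
#'
#' Divides the bleached-region intensity by the reference-region intensity
#' frame by frame — cancelling any shared acquisition-photobleaching factor —
#' then normalizes so that an unbleached region would read 1:
#' out(t) = (bleached(t) / reference(t)) * (prebleachReference /
#' prebleachBleached). The frame count is preserved.
#'
#' @param trace a [FrapTrace-class]
#' @return data.frame with columns `time` (s) and `recovery` (dimensionless,
#'   0 = fully bleached, 1 = pre-bleach level)
#' @export
correctAndNormalize <- function(trace) {
  validObject(trace)
  if (any(trace@reference <= 0))
    stop("reference intensities must be > 0 for photobleaching correction")
  rec <- (trace@bleached / trace@reference) *
    (trace@prebleachReference / trace@prebleachBleached)
  data.frame(time = trace@times, recovery = rec)
}

#' Fit the mobile fraction of a corrected FRAP curve
#'
#' Least-squares fit of the single-exponential recovery
#' y(t) = y0 + M * (1 - exp(-t / tau)) to a corrected, normalized curve.
#' The mobile fraction is M / (1 - y0) — the recovered amplitude relative to
#' the bleached depth — clipped to [0, 1]; tau is a nuisance parameter.
#' Flat curves (no recovery) return mobile fraction 0 without a fit.
#'
#' @param curve data.frame from [correctAndNormalize()], or a numeric vector
#'   of recovery values
#' @param times acquisition times, needed when `curve` is a bare vector
#' @return list: `mobileFraction`, `tau` (s), `y0`, `converged`
#' @export
fitMobileFraction <- function(curve, times = NULL) {
  if (is.data.frame(curve)) {
    times <- curve$time
    y <- curve$recovery
  } else {
    y <- as.numeric(curve)
  }
  if (is.null(times) || length(times) != length(y))
    stop("times must accompany the recovery values")
  if (length(y) < 5) stop("need >= 5 post-bleach frames to fit recovery")
  df <- data.frame(t = times, y = y)
  amp0 <- max(y) - min(y)
  if (amp0 < .Machine$double.eps^0.5)
    return(list(mobileFraction = 0, tau = NA_real_, y0 = y[1], converged = TRUE))
  tau0 <- max(diff(range(times)) / 4, min(diff(times)))
  fit <- tryCatch(
    suppressWarnings(           # port reports near-singular steps via convInfo
    stats::nls(y ~ y0 + M * (1 - exp(-t / tau)), data = df,
               start = list(y0 = min(y), M = amp0, tau = tau0),
               algorithm = "port",
               lower = c(y0 = -0.5, M = 0, tau = 1e-6),
               upper = c(y0 = 1, M = 2, tau = 1e6),
               control = stats::nls.control(maxiter = 500, warnOnly = TRUE))),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("mobile-fraction fit failed to converge: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  y0 <- unname(cf[["y0"]]); M <- unname(cf[["M"]])
  mf <- if (1 - y0 <= 0) 1 else M / (1 - y0)
  list(mobileFraction = min(max(mf, 0), 1), tau = unname(cf[["tau"]]),
       y0 = y0, converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-trace mobile fractions with a pooled summary
#'
#' FRAP curves from different GUVs are fitted individually (curves are never
#' averaged across vesicles — bleach depth and geometry vary); the pooled
#' summary reports the median and IQR of the per-trace estimates.
#'
#' @param traces list of [FrapTrace-class] objects
#' @return list: `perTrace` (data.frame of mobileFraction, tau) and
#'   `pooled` (median, IQR, n)
#' @export
mobileFractionSummary <- function(traces) {
  if (!length(traces)) stop("empty trace list")
  per <- do.call(rbind, lapply(traces, function(tr) {
    f <- fitMobileFraction(correctAndNormalize(tr))
    data.frame(mobileFraction = f$mobileFraction, tau = f$tau)
  }))
  list(perTrace = per,
       pooled = list(median = stats::median(per$mobileFraction),
                     iqr = stats::IQR(per$mobileFraction),
                     n = nrow(per)))
}
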