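#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname Roi
#' @param from,to numeric length-2 vectors, (x, y) endpoints of the profile
#'   axis in pixel coordinates
#' @param width averaging width, px
#' @export
rectRoi <- function(from, to, width = 10) {
  new("RectRoi", endpoints = rbind(as.numeric(from), as.numeric(to)),
      width = width)
}

#' @rdname Roi
#' @export
lineRoi <- function(from, to, width = 6) {
  new("LineRoi", endpoints = rbind(as.numeric(from), as.numeric(to)),
      width = width)
}

setMethod("show", "Roi", function(object) {
  cat(class(object), sprintf(": (%.1f, %.1f) -> (%.1f, %.1f), width %g px\n",
      object@endpoints[1, 1], object@endpoints[1, 2],
      object@endpoints[2, 1], object@endpoints[2, 2], object@width))
})

#' @describeIn IntensityProfile positions along the profile axis (px)
#' @param x an `IntensityProfile`
#' @export
setMethod("profilePositions", "IntensityProfile", function(x) x@positions)

#' @describeIn IntensityProfile mean intensities (a.u.)
#' @export
setMethod("profileValues", "IntensityProfile", function(x) x@values)

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile (%s): %d positions, range [%.3g, %.3g]\n",
              object@channel, length(object@values),
              min(object@values), max(object@values)))
})

#' @rdname IntensityProfile-class
#' @param positions,values,channel see slots
#' @export
intensityProfile <- function(values, positions = seq_along(values),
                             channel = "unknown") {
  new("IntensityProfile", positions = as.numeric(positions),
      values = as.numeric(values), channel = channel)
}

# Vectorised bilinear interpolation at (x, y); pixel centres at integer
# coordinates, img[row = y, col = x].
bilinearSample <- function(img, x, y) {
  nx <- ncol(img); ny <- nrow(img)
  x0 <- pmin(pmax(floor(x), 1L), nx - 1L)
  y0 <- pmin(pmax(floor(y), 1L), ny - 1L)
  fx <- x - x0
  fy <- y - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1L)]
  i10 <- img[cbind(y0 + 1L, x0)]
  i11 <- img[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Extract an averaged intensity profile from an ROI
#'
#' Samples the image at unit steps along the ROI's profile axis; each profile
#' value is the mean of `width` samples taken perpendicular to the axis
#' (bilinear interpolation for oblique ROIs; axis-aligned integer ROIs reduce
#' to plain row/column means). This reproduces the profile-averaging used in
#' manual rectangular/wide-line ROI quantification.
#'
#' @param image numeric matrix (rows = y, cols = x)
#' @param roi a [RectRoi][Roi] or [LineRoi][Roi]
#' @param channel channel label carried into the profile
#' @return an [IntensityProfile-class]
#' @export
extractProfile <- function(image, roi, channel = "unknown") {
  stopifnot(is.matrix(image), is(roi, "Roi"))
  p0 <- roi@endpoints[1, ]; p1 <- roi@endpoints[2, ]
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len < 1) stop("degenerate ROI: profile axis shorter than 1 px")
  u <- v / len                       # along profile axis
  w <- c(-u[2], u[1])                # perpendicular (averaging direction)
  nPos <- floor(len) + 1L
  tAxis <- seq(0, floor(len), by = 1)
  offs <- seq(-(roi@width - 1) / 2, (roi@width - 1) / 2, by = 1)
  xs <- outer(p0[1] + tAxis * u[1], offs * w[1], `+`)
  ys <- outer(p0[2] + tAxis * u[2], offs * w[2], `+`)
  if (min(xs) < 1 || max(xs) > ncol(image) || min(ys) < 1 || max(ys) > nrow(image))
    stop("ROI out of bounds: samples fall outside the image")
  vals <- matrix(bilinearSample(image, as.vector(xs), as.vector(ys)),
                 nPos, length(offs))
  intensityProfile(rowMeans(vals), positions = tAxis, channel = channel)
}

.profVals <- function(profile) {
  if (is(profile, "IntensityProfile")) profile@values else as.numeric(profile)
}

#' Background rules for intensity profiles
#'
#' Three background conventions used with manually drawn ROIs:
#' \describe{
#'   \item{`backgroundRect`}{rectangular-ROI rule for the protein channel in
#'     tube-pulling quantification: the average of (mean of the first `k`)
#'     and (mean of the last `k`) profile values, default `k = 15`. Accounts
#'     for protein fluorescence in solution on both sides of the membrane.}
#'   \item{`backgroundTop`}{membrane-dye rule: mean of the first `k` values
#'     only (default 15), since the dye has no signal inside the GUV.}
#'   \item{`backgroundLine`}{wide-line rule used for FRAP and tubulation
#'     assays: mean of the pooled first `k` and last `k` values, default
#'     `k = 10`.}
#' }
#' "First"/"last" are in profile order (the order positions were sampled).
#'
#' @param profile an [IntensityProfile-class] or numeric vector
#' @param k number of edge values per side
#' @return background intensity, a.u.
#' @export
backgroundRect <- function(profile, k = 15) {
  v <- .profVals(profile)
  if (length(v) < 2 * k + 1)
    stop("profile too short for rectangle rule: need >= ", 2 * k + 1,
         " values, got ", length(v))
  (mean(v[seq_len(k)]) + mean(v[seq(length(v) - k + 1, length(v))])) / 2
}

#' @rdname backgroundRect
#' @export
backgroundTop <- function(profile, k = 15) {
  v <- .profVals(profile)
  if (length(v) < k)
    stop("profile too short for top rule: need >= ", k, " values")
  mean(v[seq_len(k)])
}

#' @rdname backgroundRect
#' @export
backgroundLine <- function(profile, k = 10) {
  v <- .profVals(profile)
  if (length(v) < 2 * k + 1)
    stop("profile too short for line rule: need >= ", 2 * k + 1, " values")
  mean(c(v[seq_len(k)], v[seq(length(v) - k + 1, length(v))]))
}

# Robust noise SD of the background segments of a profile (MAD * 1.4826).
profileNoiseSd <- function(profile, k = 15) {
  v <- .profVals(profile)
  k <- min(k, floor((length(v) - 1) / 2))
  edges <- c(v[seq_len(k)], v[seq(length(v) - k + 1, length(v))])
  stats::mad(edges)
}

#' Background-subtracted peak intensity of a profile
#'
#' max(profile) minus the background from the chosen rule. A profile whose
#' peak rises less than `detectionFactor` robust noise SDs (median absolute
#' deviation of the background segments, scaled) above background is flagged
#' `belowDetection` — the operational form of "signal too low to be measured
#' (close to the noise level)"; the value is returned, not raised.
#'
#' @param profile an [IntensityProfile-class] or numeric vector
#' @param rule `"rect"`, `"top"` or `"line"`
#' @param k edge-segment length of the rule (defaults: rect/top 15, line 10)
#' @param detectionFactor threshold in units of robust noise SD (default 2)
#' @return numeric peak-minus-background with attribute `belowDetection`
#' @export
peakMinusBackground <- function(profile, rule = c("rect", "top", "line"),
                                k = NULL, detectionFactor = 2) {
  rule <- match.arg(rule)
  if (is.null(k)) k <- if (rule == "line") 10 else 15
  bg <- switch(rule,
               rect = backgroundRect(profile, k),
               top = backgroundTop(profile, k),
               line = backgroundLine(profile, k))
  v <- .profVals(profile)
  out <- max(v) - bg
  noise <- profileNoiseSd(profile, k)
  structure(out, belowDetection = (out < detectionFactor * noise))
}

#' Select the in-focus frame of a tube image series
#'
#' Replaces manual in-focus frame selection: among repeated acquisitions of
#' the same field, returns the index of the frame maximising the
#' background-subtracted membrane peak in the tube ROI (an out-of-focus tube
#' blurs and its peak drops).
#'
#' @param frames list of membrane-channel image matrices
#' @param roi tube ROI
#' @param rule background rule used for the peak (default `"top"`)
#' @return integer frame index
#' @export
selectInFocusFrame <- function(frames, roi, rule = "top") {
  if (!length(frames)) stop("empty frame list")
  peaks <- vapply(frames, function(im)
    as.numeric(peakMinusBackground(extractProfile(im, roi), rule = rule)),
    numeric(1))
  which.max(peaks)
}

#' Normalized multi-channel line profile along a polyline
#'
#' Samples each channel along a polyline (e.g. traced along a cellular
#' protrusion) with `width`-pixel perpendicular averaging, then min-max
#' normalizes each channel to [0, 1]. Distance 0 is at the first vertex (the
#' protrusion tip). A constant channel cannot be normalized; it is returned
#' as zeros with a `degenerate` attribute naming the channel.
#'
#' @param channels named list of image matrices (same dimensions)
#' @param polyline n x 2 matrix of (x, y) vertices, px
#' @param width averaging width, px (default 4)
#' @return data.frame: `distance` (px) plus one normalized column per channel;
#'   attribute `degenerate` lists constant channels, if any
#' @export
normalizedLineProfile <- function(channels, polyline, width = 4) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stop("polyline needs at least 2 vertices")
  seglen <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                          polyline[-nrow(polyline), , drop = FALSE])^2))
  if (sum(seglen) < 1) stop("degenerate (zero-length) polyline")
  out <- NULL
  degenerate <- character()
  for (nm in names(channels)) {
    vals <- numeric(); dists <- numeric()
    d0 <- 0
    for (i in seq_len(nrow(polyline) - 1)) {
      if (seglen[i] == 0) next
      roi <- lineRoi(polyline[i, ], polyline[i + 1, ], width = width)
      pr <- extractProfile(channels[[nm]], roi, channel = nm)
      keep <- if (i > 1) -1L else TRUE   # avoid double-counting shared vertex
      vals <- c(vals, pr@values[keep])
      dists <- c(dists, d0 + pr@positions[keep])
      d0 <- d0 + seglen[i]
    }
    rng <- range(vals)
    if (diff(rng) == 0) {
      norm <- rep(0, length(vals))
      degenerate <- c(degenerate, nm)
    } else {
      norm <- (vals - rng[1]) / diff(rng)
    }
    col <- data.frame(distance = dists, v = norm)
    names(col)[2] <- nm
    out <- if (is.null(out)) col else cbind(out, col[2])
  }
  attr(out, "degenerate") <- degenerate
  out
}
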