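#' @include AllClasses.R synthetic.R
NULL

#' Plain-text image export and import (16-bit PGM)
#'
#' Rendered scenes travel as portable graymap (P2, ASCII) files — one per
#' channel — with intensities linearly quantised to 16-bit unsigned range,
#' plus a JSON ground-truth sidecar when `jsonlite` is available. PGM keeps
#' the deliverables text-only while preserving the 16-bit depth of typical
#' confocal acquisitions.
#'
#' @param image numeric matrix
#' @param path output file path
#' @param maxRange intensity mapped to 65535; defaults to the image maximum
#' @return `writePgm`: invisibly, the scale factor used;
#'   `readPgm`: numeric matrix in original units (a.u.) when the scale
#'   comment is present, else raw 16-bit values
#' @export
writePgm <- function(image, path, maxRange = max(image)) {
  if (maxRange <= 0) stop("maxRange must be > 0")
  q <- pmin(pmax(round(image / maxRange * 65535), 0), 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("# scale %.10g", maxRange / 65535),
               paste(ncol(image), nrow(image)), "65535"), con)
  write(t(q), con, ncolumns = ncol(image))
  invisible(maxRange / 65535)
}

#' @rdname writePgm
#' @export
readPgm <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "P2") stop("not an ASCII PGM (P2) file")
  scale <- 1
  body <- lines[-1]
  isComment <- startsWith(trimws(body), "#")
  for (cm in body[isComment]) {
    m <- regmatches(cm, regexec("# scale ([0-9.eE+-]+)", cm))[[1]]
    if (length(m) == 2) scale <- as.numeric(m[2])
  }
  body <- body[!isComment]
  dims <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(body[-(1:2)]), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE) * scale
}

#' Write a rendered scene to a directory
#'
#' Writes `membrane.pgm`, `protein.pgm` and (requires `jsonlite`) a
#' `truth.json` sidecar holding the ground-truth record.
#'
#' @param rendered a [RenderedScene-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeScene <- function(rendered, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(rendered@membrane, rendered@protein)
  writePgm(rendered@membrane, file.path(dir, "membrane.pgm"), maxRange = mx)
  writePgm(rendered@protein, file.path(dir, "protein.pgm"), maxRange = mx)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- rendered@truth
    tr$centers <- apply(tr$centers, 1, function(r) list(x = r[1], y = r[2]))
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read and write ROI coordinate files
#'
#' ROIs are explicit inputs (mirroring manual ROI drawing); they are stored
#' as JSON: a named list of objects with fields `type` ("rect"/"line"),
#' `from`, `to` (x, y pixel coordinates) and `width`. Requires `jsonlite`.
#'
#' @param rois named list of [Roi] objects
#' @param path JSON file path
#' @return `readRois`: named list of [Roi] objects
#' @export
writeRois <- function(rois, path) {
  lst <- lapply(rois, function(r) list(
    type = if (is(r, "RectRoi")) "rect" else "line",
    from = r@endpoints[1, ], to = r@endpoints[2, ], width = r@width))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRois
#' @export
readRois <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(lst, function(r) {
    ctor <- if (identical(r$type, "rect")) rectRoi else lineRoi
    ctor(as.numeric(r$from), as.numeric(r$to), width = as.numeric(r$width))
  })
}
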