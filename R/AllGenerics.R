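#' @include AllClasses.R
NULL

#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))

#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @export
setGeneric("sortingRatio", function(m, ...) standardGeneric("sortingRatio"))

#' @export
setGeneric("bondEnergy", function(object, ...) standardGeneric("bondEnergy"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("channelImage", function(x, channel) standardGeneric("channelImage"))
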