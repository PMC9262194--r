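#' @rdname ContactMap-class
#' @param x a \linkS4class{ContactMap}.
#' @export
setGeneric("hicBins", function(x) standardGeneric("hicBins"))

#' @rdname ContactMap-class
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname ContactMap-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BackgroundFit-class
#' @param object a fit object.
#' @export
setGeneric("modelParameters", function(object, ...)
    standardGeneric("modelParameters"))

#' @rdname BackgroundFit-class
#' @export
setGeneric("binStats", function(object) standardGeneric("binStats"))

#' @rdname BackgroundFit-class
#' @export
setGeneric("maskedPairs", function(object) standardGeneric("maskedPairs"))
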