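#' @rdname ScanSet
#' @param object,x a `ScanSet`, `GGNormativeModel`, `DivergenceGrid` or
#'   `AtlasFactorSet` as appropriate.
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' @rdname ScanSet
#' @export
setGeneric("scanInfo", function(x) standardGeneric("scanInfo"))

#' @rdname ScanSet
#' @export
setGeneric("rois", function(x) standardGeneric("rois"))

#' @rdname GGNormativeModel
#' @export
setGeneric("bic", function(x) standardGeneric("bic"))

#' @rdname GGNormativeModel
#' @export
setGeneric("fpPowers", function(x) standardGeneric("fpPowers"))

#' @rdname DivergenceGrid
#' @export
setGeneric("gridAges", function(x) standardGeneric("gridAges"))

#' @rdname DivergenceGrid
#' @export
setGeneric("zStat", function(x) standardGeneric("zStat"))

#' @rdname DivergenceGrid
#' @export
setGeneric("qValue", function(x) standardGeneric("qValue"))

#' @rdname DivergenceGrid
#' @export
setGeneric("sigWindows", function(x) standardGeneric("sigWindows"))

#' @rdname AtlasFactorSet
#' @export
setGeneric("factorMaps", function(x) standardGeneric("factorMaps"))

#' @rdname AtlasFactorSet
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))
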