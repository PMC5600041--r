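#' @rdname TimeGrid-class
#' @param object,x An object.
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @rdname TimeGrid-class
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname TimeGrid-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname Curve-class
#' @param x An object.
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname Curve-class
#' @export
setGeneric("curveLabel", function(x) standardGeneric("curveLabel"))

#' @rdname PhantomVolume-class
#' @param x An object.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname PhantomVolume-class
#' @export
setGeneric("tileGeometry", function(x) standardGeneric("tileGeometry"))

#' @rdname PhantomVolume-class
#' @export
setGeneric("phantomData", function(x) standardGeneric("phantomData"))

#' @rdname PhantomVolume-class
#' @export
setGeneric("phantomAif", function(x) standardGeneric("phantomAif"))

#' @rdname PhantomVolume-class
#' @export
setGeneric("phantomVof", function(x) standardGeneric("phantomVof"))

#' @rdname PerfusionMaps-class
#' @param x An object.
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname PerfusionMaps-class
#' @export
setGeneric("methodLabel", function(x) standardGeneric("methodLabel"))

#' @rdname ResidueEstimate-class
#' @param x An object.
#' @export
setGeneric("residueValues", function(x) standardGeneric("residueValues"))
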