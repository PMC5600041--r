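#' @rdname TimeGrid-class
#' @aliases samplingInterval,TimeGrid-method
setMethod("samplingInterval", "TimeGrid", function(x) x@dt)

#' @rdname TimeGrid-class
setMethod("timePoints", "TimeGrid", function(x) x@times)

#' @rdname TimeGrid-class
setMethod("nSamples", "TimeGrid", function(x) length(x@times))

#' @rdname Curve-class
setMethod("samplingInterval", "Curve", function(x) x@grid@dt)

#' @rdname Curve-class
setMethod("timePoints", "Curve", function(x) x@grid@times)

#' @rdname Curve-class
setMethod("curveValues", "Curve", function(x) x@values)

#' @rdname Curve-class
setMethod("curveLabel", "Curve", function(x) x@label)

#' @rdname PhantomVolume-class
setMethod("groundTruth", "PhantomVolume", function(x) x@groundTruth)

#' @rdname PhantomVolume-class
setMethod("tileGeometry", "PhantomVolume", function(x) x@tileGeometry)

#' @rdname PhantomVolume-class
setMethod("phantomData", "PhantomVolume", function(x) x@data)

#' @rdname PhantomVolume-class
setMethod("phantomAif", "PhantomVolume", function(x) x@aif)

#' @rdname PhantomVolume-class
setMethod("phantomVof", "PhantomVolume", function(x) x@vof)

#' @rdname PerfusionMaps-class
setMethod("mapTable", "PerfusionMaps", function(x) x@table)

#' @rdname PerfusionMaps-class
setMethod("methodLabel", "PerfusionMaps", function(x) x@method)

#' @rdname ResidueEstimate-class
setMethod("residueValues", "ResidueEstimate", function(x) x@k)

setMethod("show", "TimeGrid", function(object) {
    cat(sprintf("TimeGrid: %d samples, dt = %g s, window [0, %g] s\n",
                length(object@times), object@dt, max(object@times)))
})

setMethod("show", "Curve", function(object) {
    cat(sprintf("Curve <%s>: %d samples, dt = %g s, range [%.4g, %.4g]\n",
                object@label, length(object@values), object@grid@dt,
                min(object@values), max(object@values)))
})

setMethod("show", "PhantomVolume", function(object) {
    d <- dim(object@data)
    cat("PhantomVolume\n")
    cat(sprintf("  data: %d slices x %d x %d voxels x %d time points\n",
                d[1], d[2], d[3], d[4]))
    cat(sprintf("  tiles: %d (%d per tissue slice)\n",
                nrow(object@groundTruth),
                nrow(object@groundTruth) / length(unique(object@groundTruth$slice))))
    cat(sprintf("  TD levels: %s s\n",
                paste(sort(unique(object@groundTruth$td)), collapse = ", ")))
    cat(sprintf("  MTT levels: %s s\n",
                paste(sort(unique(object@groundTruth$mtt)), collapse = ", ")))
    cat(sprintf("  CBV levels: %s mL/100g; shapes: %s\n",
                paste(sort(unique(object@groundTruth$cbv)), collapse = ", "),
                paste(unique(object@groundTruth$shape), collapse = ", ")))
    cat(sprintf("  noise sd: %.4g, seed: %s\n", object@config$noiseSd,
                deparse(object@config$seed)))
})

setMethod("show", "PerfusionMaps", function(object) {
    cat(sprintf("PerfusionMaps <%s>: %d tile ROIs\n", object@method,
                nrow(object@table)))
    ok <- colSums(!is.na(object@table[c("cbf", "cbv", "mtt", "td", "tmax")]))
    cat("  defined values:",
        paste(sprintf("%s=%d", names(ok), ok), collapse = " "), "\n")
})

setMethod("show", "ResidueEstimate", function(object) {
    cat(sprintf("ResidueEstimate <%s>: %d samples, threshold %.3g, peak %.4g\n",
                object@method, length(object@k), object@thresholdUsed,
                max(object@k)))
})

setMethod("show", "CalibrationFit", function(object) {
    cat(sprintf("CalibrationFit vs %s: Tmax = TD + %.4g * MTT + %.4g\n",
                object@reference, object@p, object@q))
    cat(sprintf("  n = %d (%d excluded), rms residual = %.4g s\n",
                object@nPoints, object@nExcluded, object@rmsResidual))
})

setMethod("show", "AgreementReport", function(object) {
    cat(sprintf("AgreementReport: %s vs %s (n = %d)\n",
                object@labels[1], object@labels[2], object@n))
    cat(sprintf("  r = %.4f; y = %.4f x + %.4f; %s = %.4f\n",
                object@r, object@slope, object@intercept, object@iccForm,
                object@icc))
})

setMethod("show", "BayesEstimate", function(object) {
    cat(sprintf("BayesEstimate: TD = %.3g s, MTT = %.3g s, CBF = %.4g mL/100g/min\n",
                object@td, object@mtt, object@cbf))
    cat(sprintf("  shape = %s, rss = %.4g%s\n", object@shape, object@rss,
                if (object@lowConfidence) " [low confidence]" else ""))
})
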