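#' @import methods
NULL

#' Uniform sampling grid for bolus-tracking time series
#'
#' A \code{TimeGrid} holds the sampling interval and the (endpoint-inclusive)
#' vector of sample times of a dynamic acquisition, e.g. a CT perfusion scan
#' sampled every 2 s over 60 s gives 31 samples at 0, 2, ..., 60 s.
#'
#' @slot dt Sampling interval in seconds.
#' @slot times Numeric vector of sample times, \code{times[i] = (i-1)*dt}.
#'
#' @seealso [makeTimeGrid()]
#' @export
setClass("TimeGrid", representation(dt = "numeric", times = "numeric"))

setValidity("TimeGrid", function(object) {
    msg <- character()
    if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
        msg <- c(msg, "'dt' must be a single positive number")
    if (length(object@times) < 2L)
        msg <- c(msg, "a TimeGrid needs at least 2 samples")
    else {
        expected <- (seq_along(object@times) - 1L) * object@dt
        if (max(abs(object@times - expected)) > 1e-9 * max(object@dt, 1))
            msg <- c(msg, "'times' must equal (i-1)*dt")
    }
    if (length(msg)) msg else TRUE
})

#' Sampled concentration-time curve
#'
#' Container for a single tracer concentration signal on a [TimeGrid-class]:
#' an arterial input function (AIF), venous output function (VOF), tissue
#' curve C(t), or a (scaled) residue function R(t).
#'
#' @slot grid A [TimeGrid-class].
#' @slot values Numeric vector, one value per grid sample.
#' @slot label One of \code{"aif"}, \code{"vof"}, \code{"tissue"},
#'   \code{"residue"}, \code{"scaled_residue"}.
#' @export
setClass("Curve",
    representation(grid = "TimeGrid", values = "numeric", label = "character"))

.curveLabels <- c("aif", "vof", "tissue", "residue", "scaled_residue")

setValidity("Curve", function(object) {
    msg <- character()
    if (length(object@values) != length(object@grid@times))
        msg <- c(msg, "'values' length must match the grid")
    if (!all(is.finite(object@values)))
        msg <- c(msg, "'values' must be finite")
    if (length(object@label) != 1L || !object@label %in% .curveLabels)
        msg <- c(msg, sprintf("'label' must be one of %s",
                              paste(.curveLabels, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Discrete convolution system built from an AIF
#'
#' The linear system C = A k relating the tissue curve to the scaled residue
#' function. In \code{"causal"} mode A is the lower-triangular Toeplitz matrix
#' with first column dt*AIF (used by standard SVD deconvolution); in
#' \code{"circulant"} mode the AIF is zero-padded to twice its length and
#' wrapped into a block-circulant matrix, making the deconvolution insensitive
#' to tracer arrival delay.
#'
#' @slot matrix The system matrix (N x N causal, or 2N x 2N circulant).
#' @slot dt Sampling interval in seconds.
#' @slot mode \code{"causal"} or \code{"circulant"}.
#' @export
setClass("ConvolutionSystem",
    representation(matrix = "matrix", dt = "numeric", mode = "character"))

setValidity("ConvolutionSystem", function(object) {
    if (!object@mode %in% c("causal", "circulant"))
        return("'mode' must be 'causal' or 'circulant'")
    if (nrow(object@matrix) != ncol(object@matrix))
        return("system matrix must be square")
    TRUE
})

#' Deconvolved scaled residue function
#'
#' Result of SVD-family deconvolution: the estimate of k(t) = CBF * R(t)
#' (flow-scaled residue function), truncated back to the acquisition length
#' for circulant systems. Oscillations in k are the known artifact of SVD
#' deconvolution; the truncation threshold actually used is recorded.
#'
#' @slot k Numeric vector, the scaled residue estimate (per-second flow units).
#' @slot grid The [TimeGrid-class] of the acquisition.
#' @slot method \code{"ssvd"}, \code{"bsvd"} or \code{"osvd"}.
#' @slot thresholdUsed Singular-value truncation fraction actually applied.
#' @export
setClass("ResidueEstimate",
    representation(k = "numeric", grid = "TimeGrid", method = "character",
                   thresholdUsed = "numeric"))

#' Digital perfusion phantom volume
#'
#' A 4-D synthetic bolus-tracking volume with known ground truth. Tissue
#' slices hold a grid of square tiles, one per (TD, MTT) combination; CBV and
#' residue shape vary across slices; a dedicated final slice carries the
#' global AIF and VOF. Every voxel of a tile is an independent noise
#' realization of the same noiseless tissue curve.
#'
#' @slot data 4-D array indexed (slice, row, col, time).
#' @slot grid The acquisition [TimeGrid-class].
#' @slot tileGeometry \code{data.frame} mapping each tile to its slice and
#'   voxel block (columns \code{slice, tile, row0, col0, size}).
#' @slot groundTruth \code{data.frame} of true per-tile parameters
#'   (\code{slice, tile, td, mtt, cbv, cbf, shape}).
#' @slot aif,vof The global arterial input / venous output [Curve-class]s.
#' @slot config The [phantomConfig()] list used to build the volume.
#' @seealso [buildPhantom()]
#' @export
setClass("PhantomVolume",
    representation(data = "array", grid = "TimeGrid",
                   tileGeometry = "data.frame", groundTruth = "data.frame",
                   aif = "Curve", vof = "Curve", config = "list"))

setValidity("PhantomVolume", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
        msg <- c(msg, "'data' must be a 4-D array (slice, row, col, time)")
    else if (dim(object@data)[4L] != length(object@grid@times))
        msg <- c(msg, "4th dimension of 'data' must match the time grid")
    need <- c("slice", "tile", "row0", "col0", "size")
    if (!all(need %in% names(object@tileGeometry)))
        msg <- c(msg, "tileGeometry missing required columns")
    needGt <- c("slice", "tile", "td", "mtt", "cbv", "cbf", "shape")
    if (!all(needGt %in% names(object@groundTruth)))
        msg <- c(msg, "groundTruth missing required columns")
    if (length(msg)) msg else TRUE
})

#' Per-tile (or per-voxel) perfusion parameter maps
#'
#' Tabular perfusion estimates produced by one deconvolution method, one row
#' per tile ROI: CBF (mL/100g/min), CBV (mL/100g), MTT (s), Tmax (s) and,
#' for the Bayesian estimator, the tracer arrival delay TD (s). Columns not
#' produced by a method are NA.
#'
#' @slot table \code{data.frame} with columns
#'   \code{slice, tile, cbf, cbv, mtt, td, tmax}.
#' @slot method Method label, e.g. \code{"bsvd"} or \code{"bayesian"}.
#' @slot params List of the estimation settings used (threshold, grids, ...).
#' @export
setClass("PerfusionMaps",
    representation(table = "data.frame", method = "character",
                   params = "list"))

setValidity("PerfusionMaps", function(object) {
    need <- c("slice", "tile", "cbf", "cbv", "mtt", "td", "tmax")
    if (!all(need %in% names(object@table)))
        return(sprintf("map table must contain columns %s",
                       paste(need, collapse = ", ")))
    TRUE
})

#' Calibration constants relating Tmax to TD and MTT
#'
#' Least-squares fit of the linear relation Tmax = TD + p*MTT + q against a
#' reference Tmax map. \code{p} is unitless, \code{q} is in seconds; both are
#' specific to the reference deconvolution algorithm.
#'
#' @slot p,q Fitted constants.
#' @slot reference Label of the reference Tmax (e.g. \code{"bsvd"}).
#' @slot nPoints Number of (TD, MTT, Tmax) triples used.
#' @slot nExcluded Pairs dropped for non-finite values.
#' @slot rmsResidual Root-mean-square residual of the fit, in seconds.
#' @seealso [fitPQ()], [applyPQ()]
#' @export
setClass("CalibrationFit",
    representation(p = "numeric", q = "numeric", reference = "character",
                   nPoints = "integer", nExcluded = "integer",
                   rmsResidual = "numeric"))

setValidity("CalibrationFit", function(object) {
    msg <- character()
    if (!is.finite(object@p) || !is.finite(object@q))
        msg <- c(msg, "'p' and 'q' must be finite")
    if (object@nPoints < 3L)
        msg <- c(msg, "a calibration needs at least 3 points")
    if (length(msg)) msg else TRUE
})

#' Method-agreement statistics for paired measurements
#'
#' Pearson correlation, ordinary least-squares regression (y on x) and the
#' intraclass correlation coefficient in its two-way random-effects,
#' absolute-agreement, single-measures form ICC(2,1) for one pair of
#' measurement sets.
#'
#' @slot r Pearson product-moment correlation.
#' @slot slope,intercept OLS regression of y on x.
#' @slot icc ICC(2,1) unless \code{iccForm} says otherwise.
#' @slot iccForm \code{"ICC(2,1)"} or \code{"ICC(3,1)"}.
#' @slot n Number of complete pairs used.
#' @slot labels Length-2 character: the x and y labels.
#' @seealso [agreementReport()]
#' @export
setClass("AgreementReport",
    representation(r = "numeric", slope = "numeric", intercept = "numeric",
                   icc = "numeric", iccForm = "character", n = "integer",
                   labels = "character"))

setValidity("AgreementReport", function(object) {
    msg <- character()
    if (is.finite(object@r) && abs(object@r) > 1 + 1e-12)
        msg <- c(msg, "'r' must lie in [-1, 1]")
    if (is.finite(object@icc) && abs(object@icc) > 1 + 1e-12)
        msg <- c(msg, "'icc' must lie in [-1, 1]")
    if (object@n < 3L)
        msg <- c(msg, "need at least 3 pairs")
    if (length(msg)) msg else TRUE
})

#' Bayesian per-curve estimate
#'
#' Summary of the grid posterior for one tissue curve: tracer arrival delay,
#' mean transit time, flow, the residue shape with highest model evidence,
#' and the residual sum of squares at the posterior mode.
#'
#' @slot td,mtt,cbf Point estimates (s, s, mL/100g/min).
#' @slot shape Selected residue shape.
#' @slot logEvidence Named numeric, log model evidence per candidate shape.
#' @slot rss Residual sum of squares at the MAP grid point.
#' @slot lowConfidence TRUE when the curve enhancement is within noise.
#' @seealso [bayesFitCurve()]
#' @export
setClass("BayesEstimate",
    representation(td = "numeric", mtt = "numeric", cbf = "numeric",
                   shape = "character", logEvidence = "numeric",
                   rss = "numeric", lowConfidence = "logical"))
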