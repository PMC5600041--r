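#' Build the discrete convolution system from an AIF
#'
#' @param aif The global AIF [Curve-class].
#' @param mode \code{"causal"} for the lower-triangular Toeplitz system used
#'   by standard SVD, or \code{"circulant"} for the zero-padded (2N)
#'   block-circulant system that makes deconvolution delay-insensitive.
#' @return A [ConvolutionSystem-class].
#' @export
buildConvolutionSystem <- function(aif, mode = c("causal", "circulant")) {
    stopifnot(is(aif, "Curve"))
    mode <- match.arg(mode)
    a <- aif@values
    if (all(a == 0)) stop("AIF is identically zero")
    dt <- aif@grid@dt
    n <- length(a)
    if (mode == "causal") {
        A <- matrix(0, n, n)
        for (j in seq_len(n)) A[j:n, j] <- dt * a[seq_len(n - j + 1L)]
    } else {
        ap <- c(a, rep(0, n))
        m <- 2L * n
        idx <- outer(seq_len(m), seq_len(m), function(i, j) ((i - j) %% m) + 1L)
        A <- matrix(dt * ap[idx], m, m)
    }
    new("ConvolutionSystem", matrix = A, dt = dt, mode = mode)
}

# Truncated-SVD pseudoinverse of a convolution system at a given relative
# singular-value threshold. Returns NULL when every singular value is cut.
.truncatedPinv <- function(sv, threshold) {
    keep <- sv$d >= threshold * max(sv$d)
    if (!any(keep)) return(NULL)
    dInv <- ifelse(keep, 1 / sv$d, 0)
    sv$v %*% (dInv * t(sv$u))
}

.oscillationIndex <- function(k) {
    pk <- max(k)
    if (pk <= 0) return(Inf)
    sum(abs(diff(k, differences = 2))) / (2 * length(k) * pk)
}

#' SVD-family deconvolution of a tissue curve
#'
#' Solves C = A k for the flow-scaled residue function k(t) = CBF * R(t) by
#' truncated singular value decomposition of the AIF convolution matrix.
#' \code{"ssvd"} uses the causal Toeplitz system; \code{"bsvd"} the
#' block-circulant system (tissue curve zero-padded to 2N, estimate truncated
#' back to N), which tolerates tracer arrival delay; \code{"osvd"} is bsvd
#' with the truncation raised per curve until the oscillation index
#' \eqn{OI = \frac{1}{2N \max k} \sum_i |k_i - 2k_{i-1} + k_{i-2}|}
#' falls below \code{oiLimit}. Negative values of k are kept (no clipping).
#'
#' @param ct Tissue [Curve-class] on the same grid as \code{aif}.
#' @param aif Global AIF [Curve-class].
#' @param method \code{"bsvd"} (default), \code{"ssvd"} or \code{"osvd"}.
#' @param threshold Relative singular-value cutoff in [0, 1): singular values
#'   below \code{threshold * max(d)} are zeroed. For osvd this is the
#'   starting value.
#' @param oiLimit Oscillation-index limit for osvd.
#' @param system Optional precomputed [ConvolutionSystem-class] (and its SVD,
#'   see [deconvolveVolume()]) to avoid refactorizing per curve.
#' @return A [ResidueEstimate-class].
#' @export
svdDeconvolve <- function(ct, aif, method = c("bsvd", "ssvd", "osvd"),
                          threshold = 0.15, oiLimit = 0.035, system = NULL) {
    stopifnot(is(ct, "Curve"), is(aif, "Curve"))
    method <- match.arg(method)
    if (!isTRUE(all.equal(ct@grid@times, aif@grid@times)))
        stop("tissue curve and AIF must share the same time grid")
    if (threshold < 0 || threshold >= 1)
        stop("'threshold' must lie in [0, 1)")
    mode <- if (method == "ssvd") "causal" else "circulant"
    if (is.null(system)) system <- buildConvolutionSystem(aif, mode)
    if (system@mode != mode) stop("system mode does not match method")
    sv <- attr(system, "svd")
    if (is.null(sv)) sv <- svd(system@matrix)
    n <- length(ct@values)
    c <- if (mode == "circulant") c(ct@values, rep(0, n)) else ct@values

    solveAt <- function(th) {
        P <- .truncatedPinv(sv, th)
        if (is.null(P)) return(NULL)
        drop(P %*% c)
    }
    k <- solveAt(threshold)
    used <- threshold
    if (is.null(k)) {
        warning("truncation removed every singular value; returning zero residue")
        k <- numeric(length(c))
    } else if (method == "osvd") {
        while (.oscillationIndex(k[seq_len(n)]) > oiLimit && used < 0.95) {
            used <- used + 0.01
            knew <- solveAt(used)
            if (is.null(knew)) break
            k <- knew
        }
    }
    new("ResidueEstimate", k = k[seq_len(n)], grid = ct@grid,
        method = method, thresholdUsed = used)
}

# Peak time of the residue estimate. refine = "none": first maximum, earliest
# wins on ties. "parabolic": sub-sample vertex of the parabola through the
# peak and its two neighbours (offset clamped to half a sample). "centroid"
# (default): intensity-weighted centroid of the contiguous supra-half-maximum
# region around the peak, falling back to the parabola when that region is a
# single sample. The centroid is continuous in the data, so it does not jump
# between near-equal ripple lobes of flat-topped residue estimates the way a
# plain argmax (or the 3-point parabola) does.
.tmaxFromK <- function(k, times, refine = c("centroid", "parabolic", "none")) {
    if (is.logical(refine)) refine <- if (refine) "centroid" else "none"
    refine <- match.arg(refine)
    p <- which.max(k)
    parab <- function() {
        tmax <- times[p]
        if (p > 1L && p < length(k)) {
            y0 <- k[p - 1L]; y1 <- k[p]; y2 <- k[p + 1L]
            den <- y0 - 2 * y1 + y2
            if (den < 0) {
                delta <- 0.5 * (y0 - y2) / den
                delta <- max(-0.5, min(0.5, delta))
                tmax <- tmax + delta * (times[2L] - times[1L])
            }
        }
        tmax
    }
    tmax <- switch(refine,
        none = times[p],
        parabolic = parab(),
        centroid = {
            half <- 0.5 * k[p]
            lo <- p; while (lo > 1L && k[lo - 1L] >= half) lo <- lo - 1L
            hi <- p; while (hi < length(k) && k[hi + 1L] >= half) hi <- hi + 1L
            if (lo == hi) parab()
            else {
                w <- k[lo:hi] - half
                sum(w * times[lo:hi]) / sum(w)
            }
        })
    max(0, tmax)
}

#' Perfusion maps from a deconvolved residue function
#'
#' Extracts the standard metrics: CBF as the peak of k converted to
#' mL/100g/min (factor 100 g-to-100g times 60 s-to-min), Tmax as the time of
#' the first maximum of k (sub-sample refinement on by default), CBV from
#' the tracer-conservation area ratio 100*area(C)/area(AIF) (trapezoidal),
#' and MTT = 60*CBV/CBF by the central volume principle.
#'
#' @param est A [ResidueEstimate-class].
#' @param ct,aif The tissue curve and AIF the estimate came from.
#' @param refine Sub-sample refinement of the peak time:
#'   \code{"centroid"} (default) takes the intensity-weighted centroid of
#'   the contiguous supra-half-maximum region around the peak — continuous
#'   in the data, so it stays stable when truncated-SVD ripple makes
#'   flat-topped residue estimates carry several near-equal lobes —
#'   falling back to \code{"parabolic"} (vertex of the parabola through the
#'   discrete peak and its neighbours) for single-sample peaks;
#'   \code{"none"} gives the strict grid argmax, earliest sample on ties.
#'   \code{TRUE}/\code{FALSE} are accepted as aliases for the default
#'   refinement / \code{"none"}.
#' @return One-row \code{data.frame} with columns
#'   \code{cbf, cbv, mtt, td, tmax} (td is NA: SVD methods do not estimate
#'   it separately). All NA with a warning when the residue peak is not
#'   positive.
#' @export
mapsFromResidue <- function(est, ct, aif, refine = "centroid") {
    stopifnot(is(est, "ResidueEstimate"), is(ct, "Curve"), is(aif, "Curve"))
    k <- est@k
    times <- est@grid@times
    if (max(k) <= 0) {
        warning("non-positive residue peak; maps undefined")
        return(data.frame(cbf = NA_real_, cbv = NA_real_, mtt = NA_real_,
                          td = NA_real_, tmax = NA_real_))
    }
    cbf <- max(k) * 100 * 60
    tmax <- .tmaxFromK(k, times, refine)
    cbv <- 100 * .trapz(times, ct@values) / .trapz(times, aif@values)
    data.frame(cbf = cbf, cbv = cbv, mtt = 60 * cbv / cbf,
               td = NA_real_, tmax = tmax)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# Mean tissue curve of every tile, as an nSamples x nTiles matrix in
# groundTruth row order.
.tileMeanCurves <- function(phantom) {
    geom <- phantom@tileGeometry
    d <- phantom@data
    nT <- dim(d)[4L]
    out <- matrix(0, nT, nrow(geom))
    for (r in seq_len(nrow(geom))) {
        rows <- geom$row0[r] + seq_len(geom$size[r])
        cols <- geom$col0[r] + seq_len(geom$size[r])
        block <- d[geom$slice[r], rows, cols, , drop = FALSE]
        out[, r] <- apply(block, 4L, mean)
    }
    out
}

#' Deconvolve a phantom volume with an SVD-family method
#'
#' Runs [svdDeconvolve()] + [mapsFromResidue()] on every tile of a phantom.
#' The SVD of the AIF system is factorized once and reused for all curves.
#'
#' @param phantom A [PhantomVolume-class].
#' @param method,threshold,oiLimit See [svdDeconvolve()].
#' @param roiMode \code{"tile_mean"} (deconvolve the mean curve of each tile,
#'   default) or \code{"per_voxel"} (deconvolve every voxel, then average the
#'   maps over each tile).
#' @param refine See [mapsFromResidue()].
#' @return A [PerfusionMaps-class] with one row per tile, in ground-truth
#'   row order.
#' @export
deconvolveVolume <- function(phantom, method = c("bsvd", "ssvd", "osvd"),
                             threshold = 0.15, oiLimit = 0.035,
                             roiMode = c("tile_mean", "per_voxel"),
                             refine = "centroid") {
    stopifnot(is(phantom, "PhantomVolume"))
    method <- match.arg(method)
    roiMode <- match.arg(roiMode)
    aif <- phantom@aif
    mode <- if (method == "ssvd") "causal" else "circulant"
    system <- buildConvolutionSystem(aif, mode)
    attr(system, "svd") <- svd(system@matrix)

    # Many curves share one AIF system: solve them in a single matrix
    # product with the truncated pseudoinverse (osvd adapts its truncation
    # per curve and takes the per-curve path).
    fitMatrix <- function(C) {   # C: nSamples x nCurves
        n <- nrow(C)
        if (method == "osvd") {
            K <- vapply(seq_len(ncol(C)), function(j) {
                ct <- new("Curve", grid = phantom@grid, values = C[, j],
                          label = "tissue")
                svdDeconvolve(ct, aif, method, threshold, oiLimit,
                              system = system)@k
            }, numeric(n))
        } else {
            P <- .truncatedPinv(attr(system, "svd"), threshold)
            if (is.null(P)) stop("truncation removed every singular value")
            Cin <- if (system@mode == "circulant")
                rbind(C, matrix(0, n, ncol(C))) else C
            K <- (P %*% Cin)[seq_len(n), , drop = FALSE]
        }
        aifArea <- .trapz(phantom@grid@times, aif@values)
        times <- phantom@grid@times
        do.call(rbind, lapply(seq_len(ncol(C)), function(j) {
            k <- K[, j]
            if (max(k) <= 0)
                return(data.frame(cbf = NA_real_, cbv = NA_real_,
                                  mtt = NA_real_, td = NA_real_,
                                  tmax = NA_real_))
            cbv <- 100 * .trapz(times, C[, j]) / aifArea
            cbf <- max(k) * 100 * 60
            data.frame(cbf = cbf, cbv = cbv, mtt = 60 * cbv / cbf,
                       td = NA_real_, tmax = .tmaxFromK(k, times, refine))
        }))
    }
    geom <- phantom@tileGeometry
    if (roiMode == "tile_mean") {
        rows <- fitMatrix(.tileMeanCurves(phantom))
    } else {
        rows <- do.call(rbind, lapply(seq_len(nrow(geom)), function(r) {
            vr <- geom$row0[r] + seq_len(geom$size[r])
            vc <- geom$col0[r] + seq_len(geom$size[r])
            block <- phantom@data[geom$slice[r], vr, vc, , drop = FALSE]
            per <- fitMatrix(t(matrix(block, ncol = dim(block)[4L])))
            as.data.frame(t(colMeans(per, na.rm = TRUE)))
        }))
    }
    tab <- cbind(geom[c("slice", "tile")], rows)
    rownames(tab) <- NULL
    new("PerfusionMaps", table = tab, method = method,
        params = list(threshold = threshold, oiLimit = oiLimit,
                      roiMode = roiMode, refine = refine))
}
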