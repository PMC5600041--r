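#' Search grid for the Bayesian tracer-kinetic estimator
#'
#' Defaults span the physiological ranges of the phantom with margin: tracer
#' arrival delays 0 to 5 s in 0.1-s steps, 120 log-spaced mean transit times
#' between 1 and 40 s (a 2.3 percent grid step, so MTT quantization stays
#' well below the estimator's precision and the delay/duration trade-off of
#' compact residue shapes stays near the delay-grid resolution), and all
#' three candidate residue shapes.
#'
#' @param tdGrid Candidate delays (s, sorted, non-negative).
#' @param mttGrid Candidate mean transit times (s, sorted, positive).
#' @param shapes Candidate residue shapes considered for model selection.
#' @param summary \code{"posterior_mean"} (default; sub-grid resolution) or
#'   \code{"map"} (maximum a posteriori grid point).
#' @return A list of class \code{"BayesSearchSpec"}.
#' @export
bayesSearchSpec <- function(tdGrid = seq(0, 5, by = 0.1),
                            mttGrid = exp(seq(log(1), log(40),
                                              length.out = 120)),
                            shapes = c("exponential", "linear", "box"),
                            summary = c("posterior_mean", "map")) {
    if (!length(tdGrid) || !length(mttGrid))
        stop("'tdGrid' and 'mttGrid' must be non-empty")
    if (is.unsorted(tdGrid) || is.unsorted(mttGrid))
        stop("grids must be sorted increasing")
    if (any(tdGrid < 0) || any(mttGrid <= 0))
        stop("need tdGrid >= 0 and mttGrid > 0")
    shapes <- vapply(shapes, match.arg,
                     c("exponential", "linear", "box"), FUN.VALUE = "")
    spec <- list(tdGrid = as.numeric(tdGrid), mttGrid = as.numeric(mttGrid),
                 shapes = unname(shapes), summary = match.arg(summary))
    class(spec) <- "BayesSearchSpec"
    spec
}

# Unit-amplitude model bank: every (shape, mtt, td) combination as a column
# of an nSamples x K matrix, plus its squared norms and the grid bookkeeping.
# Models are evaluated on the fine internal grid (see .tissueModelFine); the
# td shift is applied to the precomputed fine (aif * residue-kernel)
# convolution -- shifting commutes with the causal convolution, so this
# equals shifting the AIF first -- and the result sampled back to the
# acquisition grid.
.basisCache <- new.env(parent = emptyenv())

.bayesBasis <- function(aif, spec) {
    key <- list(aif = aif@values, times = aif@grid@times,
                grids = spec[c("tdGrid", "mttGrid", "shapes")])
    if (!is.null(.basisCache$key) && identical(.basisCache$key, key))
        return(.basisCache$value)
    grid <- aif@grid
    n <- nSamples(grid)
    dtF <- grid@dt / .OVERSAMPLE
    aifFine <- .upsampleAif(aif@values, grid)
    tF <- .fineTimes(grid)
    meta <- expand.grid(td = spec$tdGrid, mtt = spec$mttGrid,
                        shape = spec$shapes, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    base <- list()
    for (sh in spec$shapes)
        for (m in spec$mttGrid)
            base[[paste(sh, m)]] <-
                .convolveCausal(aifFine, .residueKernelAt(sh, m, tF, dtF),
                                dtF)
    M <- matrix(0, n, nrow(meta))
    for (i in seq_len(nrow(meta)))
        M[, i] <- .downsample(.shiftCurve(base[[paste(meta$shape[i],
                                                      meta$mtt[i])]],
                                          meta$td[i], dtF))
    out <- list(M = M, meta = meta, mm = colSums(M^2))
    .basisCache$key <- key
    .basisCache$value <- out
    out
}

# Vectorized grid-posterior fit of many curves at once. C is an
# nSamples x nCurves matrix. For each curve and each grid model m the
# amplitude is profiled analytically (a* = <C,m>/<m,m>, clamped at 0); with
# the Gaussian noise scale marginalized under a Jeffreys prior and flat
# priors on the grid, the marginal posterior of each grid point is
# proportional to RSS^(-(N-1)/2).
.bayesFitMatrix <- function(C, aif, spec, basis = NULL) {
    if (is.null(basis)) basis <- .bayesBasis(aif, spec)
    M <- basis$M; meta <- basis$meta; mm <- basis$mm
    n <- nrow(C); nc <- ncol(C)
    cn2 <- colSums(C^2)
    CtM <- crossprod(C, M)                       # nCurves x K
    A <- sweep(CtM, 2L, mm, "/")                 # profiled amplitudes
    A[A < 0] <- 0
    RSS <- pmax(cn2 - A * CtM, 0)                # = cn2 - <C,m>^2/mm if a*>0
    RSS[A == 0] <- cn2[row(RSS)[A == 0]]
    floorv <- pmax(cn2 * 1e-28, .Machine$double.xmin)
    logw <- -(n - 1) / 2 * log(pmax(RSS, floorv[row(RSS)]))

    shapeIdx <- split(seq_len(nrow(meta)), meta$shape)
    out <- data.frame(td = numeric(nc), mtt = numeric(nc), cbf = numeric(nc),
                      shape = character(nc), rss = numeric(nc),
                      lowConfidence = logical(nc))
    logEv <- matrix(NA_real_, nc, length(shapeIdx),
                    dimnames = list(NULL, names(shapeIdx)))
    for (ci in seq_len(nc)) {
        lw <- logw[ci, ]
        ev <- vapply(shapeIdx, function(ix) .logSumExp(lw[ix]), 0)
        logEv[ci, ] <- ev
        best <- names(shapeIdx)[which.max(ev)]
        ix <- shapeIdx[[best]]
        w <- exp(lw[ix] - .logSumExp(lw[ix]))
        mapIx <- ix[which.max(lw[ix])]
        if (spec$summary == "posterior_mean") {
            out$td[ci] <- sum(w * meta$td[ix])
            out$mtt[ci] <- sum(w * meta$mtt[ix])
        } else {
            out$td[ci] <- meta$td[mapIx]
            out$mtt[ci] <- meta$mtt[mapIx]
        }
        out$shape[ci] <- best
        out$cbf[ci] <- 6000 * A[ci, mapIx]       # mL/g/s -> mL/100g/min
        out$rss[ci] <- RSS[ci, mapIx]
        # enhancement below 3x a robust noise estimate from the pre-bolus
        # residual spread
        sigma <- sqrt(RSS[ci, mapIx] / max(n - 3, 1))
        out$lowConfidence[ci] <- max(C[, ci]) < 3 * sigma
    }
    attr(out, "logEvidence") <- logEv
    out
}

.logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

#' Bayesian fit of a single tissue curve
#'
#' Grid posterior over (TD, MTT, residue shape) under the parametric
#' tracer-kinetic forward model C(t) = a (AIF(. - TD) x R_MTT,shape)(t):
#' the amplitude a (= CBF) is profiled analytically per grid point, the
#' Gaussian noise scale is marginalized under a Jeffreys prior, and flat
#' priors are placed on the grid, giving a marginal posterior proportional
#' to RSS^(-(N-1)/2). The residue shape is chosen by highest model evidence;
#' TD and MTT are summarized by their posterior mean over the winning
#' shape's grid (or the MAP point).
#'
#' @param ct Tissue [Curve-class].
#' @param aif Global AIF [Curve-class] on the same grid.
#' @param spec A [bayesSearchSpec()].
#' @param details Logical; when TRUE, attach the normalized grid posterior
#'   of the selected shape as attribute \code{"posterior"} (a data.frame
#'   with columns td, mtt, posterior).
#' @return A [BayesEstimate-class]. Curves whose peak enhancement is within
#'   3x the estimated noise level are flagged low-confidence (estimates are
#'   still returned).
#' @export
bayesFitCurve <- function(ct, aif, spec = bayesSearchSpec(),
                          details = FALSE) {
    stopifnot(is(ct, "Curve"), is(aif, "Curve"))
    if (!isTRUE(all.equal(ct@grid@times, aif@grid@times)))
        stop("tissue curve and AIF must share the same time grid")
    basis <- .bayesBasis(aif, spec)
    fit <- .bayesFitMatrix(matrix(ct@values, ncol = 1), aif, spec, basis)
    est <- new("BayesEstimate", td = fit$td, mtt = fit$mtt, cbf = fit$cbf,
               shape = fit$shape, rss = fit$rss,
               logEvidence = drop(attr(fit, "logEvidence")[1, ]),
               lowConfidence = fit$lowConfidence)
    if (details) {
        # recompute the winning shape's normalized posterior for inspection
        ix <- which(basis$meta$shape == fit$shape)
        mm <- basis$mm[ix]
        ctm <- drop(crossprod(basis$M[, ix], ct@values))
        a <- pmax(ctm / mm, 0)
        rss <- pmax(sum(ct@values^2) - a * ctm, 0)
        rss[a == 0] <- sum(ct@values^2)
        lw <- -(length(ct@values) - 1) / 2 *
            log(pmax(rss, sum(ct@values^2) * 1e-28))
        post <- exp(lw - .logSumExp(lw))
        attr(est, "posterior") <- data.frame(td = basis$meta$td[ix],
                                             mtt = basis$meta$mtt[ix],
                                             posterior = post)
    }
    est
}

#' Bayesian fit of a phantom volume
#'
#' Produces TD, MTT and CBF maps per tile. In \code{"tile_mean"} mode
#' (default) the voxel curves of each tile are averaged and fit once; in
#' \code{"per_voxel"} mode every voxel is fit and the resulting maps are
#' averaged per tile.
#'
#' @param phantom A [PhantomVolume-class].
#' @param spec A [bayesSearchSpec()].
#' @param roiMode \code{"tile_mean"} or \code{"per_voxel"}.
#' @return A [PerfusionMaps-class] with method label \code{"bayesian"}
#'   (columns \code{td, mtt, cbf} populated; \code{tmax} stays NA until
#'   calibrated with [applyPQ()]).
#' @export
bayesFitVolume <- function(phantom, spec = bayesSearchSpec(),
                           roiMode = c("tile_mean", "per_voxel")) {
    stopifnot(is(phantom, "PhantomVolume"))
    roiMode <- match.arg(roiMode)
    geom <- phantom@tileGeometry
    if (!nrow(geom)) stop("phantom has no tiles")
    basis <- .bayesBasis(phantom@aif, spec)
    if (roiMode == "tile_mean") {
        C <- .tileMeanCurves(phantom)
        fit <- .bayesFitMatrix(C, phantom@aif, spec, basis)
    } else {
        rows <- vector("list", nrow(geom))
        for (r in seq_len(nrow(geom))) {
            vr <- geom$row0[r] + seq_len(geom$size[r])
            vc <- geom$col0[r] + seq_len(geom$size[r])
            block <- phantom@data[geom$slice[r], vr, vc, , drop = FALSE]
            vox <- t(matrix(block, ncol = dim(block)[4L]))  # time x voxels
            per <- .bayesFitMatrix(vox, phantom@aif, spec, basis)
            rows[[r]] <- data.frame(td = mean(per$td), mtt = mean(per$mtt),
                                    cbf = mean(per$cbf))
        }
        fit <- do.call(rbind, rows)
    }
    tab <- data.frame(slice = geom$slice, tile = geom$tile,
                      cbf = fit$cbf, cbv = fit$cbf * fit$mtt / 60,
                      mtt = fit$mtt, td = fit$td, tmax = NA_real_,
                      shape = if (roiMode == "tile_mean") fit$shape
                              else NA_character_)
    new("PerfusionMaps", table = tab, method = "bayesian",
        params = list(tdGrid = spec$tdGrid, mttGrid = spec$mttGrid,
                      shapes = spec$shapes, summary = spec$summary,
                      roiMode = roiMode))
}
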