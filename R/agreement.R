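#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the argument checks used throughout
#' the agreement analyses.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return The correlation coefficient.
#' @export
pearsonR <- function(x, y) {
    .checkPairs(x, y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined statistic: zero variance")
    stats::cor(x, y)
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y Numeric vectors of equal length >= 3; x must vary.
#' @return List with elements \code{slope} and \code{intercept}.
#' @export
linReg <- function(x, y) {
    .checkPairs(x, y)
    if (stats::sd(x) == 0)
        stop("degenerate design: 'x' is constant")
    co <- stats::coef(stats::lm(y ~ x))
    list(slope = unname(co[2L]), intercept = unname(co[1L]))
}

.checkPairs <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    if (length(x) < 3L) stop("need at least 3 pairs")
    if (anyNA(x) || anyNA(y)) stop("pairs must be complete (no NA)")
    invisible(TRUE)
}

#' Intraclass correlation coefficient for two raters
#'
#' Computed from the two-way ANOVA decomposition of the n x 2 data matrix.
#' The default form is ICC(2,1): two-way random effects, absolute agreement,
#' single measures — the standard choice for method-agreement studies, since
#' it penalizes systematic bias between the methods. ICC(3,1) (two-way
#' mixed, consistency) is available behind the \code{form} flag.
#'
#' @param x,y Paired measurements (the two "raters"), equal length >= 3.
#' @param form \code{"ICC(2,1)"} (default) or \code{"ICC(3,1)"}.
#' @return The intraclass correlation coefficient.
#' @export
iccAbsolute <- function(x, y, form = c("ICC(2,1)", "ICC(3,1)")) {
    .checkPairs(x, y)
    form <- match.arg(form)
    n <- length(x); k <- 2
    dat <- cbind(x, y)
    grand <- mean(dat)
    if (sum((dat - grand)^2) == 0)
        stop("undefined statistic: zero total variance")
    rowM <- rowMeans(dat); colM <- colMeans(dat)
    ssRows <- k * sum((rowM - grand)^2)
    ssCols <- n * sum((colM - grand)^2)
    ssTot <- sum((dat - grand)^2)
    ssErr <- ssTot - ssRows - ssCols
    msr <- ssRows / (n - 1)
    msc <- ssCols / (k - 1)
    mse <- ssErr / ((n - 1) * (k - 1))
    if (form == "ICC(2,1)")
        (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    else
        (msr - mse) / (msr + (k - 1) * mse)
}

#' Per-tile ROI means of a voxel map
#'
#' Arithmetic mean of the voxel values inside each square tile, excluding
#' NaN/NA voxels and reporting how many were excluded.
#'
#' @param mapVolume 3-D array (slice, row, col) of per-voxel values.
#' @param geometry Tile geometry \code{data.frame} as in
#'   [tileGeometry()] (columns slice, tile, row0, col0, size).
#' @return \code{data.frame} with columns
#'   \code{slice, tile, mean, nExcluded}.
#' @export
tileMeans <- function(mapVolume, geometry) {
    stopifnot(length(dim(mapVolume)) == 3L)
    need <- c("slice", "tile", "row0", "col0", "size")
    if (!all(need %in% names(geometry)))
        stop("geometry missing required columns")
    out <- geometry[c("slice", "tile")]
    out$mean <- NA_real_
    out$nExcluded <- NA_integer_
    for (r in seq_len(nrow(geometry))) {
        rows <- geometry$row0[r] + seq_len(geometry$size[r])
        cols <- geometry$col0[r] + seq_len(geometry$size[r])
        if (max(rows) > dim(mapVolume)[2L] || max(cols) > dim(mapVolume)[3L] ||
            geometry$slice[r] > dim(mapVolume)[1L])
            stop("geometry does not fit inside the map volume")
        v <- mapVolume[geometry$slice[r], rows, cols]
        if (!length(v)) stop("empty tile")
        bad <- !is.finite(v)
        out$mean[r] <- mean(v[!bad])
        out$nExcluded[r] <- sum(bad)
    }
    rownames(out) <- NULL
    out
}

#' Full agreement report for one pair of measurements
#'
#' Bundles Pearson r, the OLS regression of y on x (reference on x,
#' comparison method on y), and ICC into one [AgreementReport-class].
#' Non-finite pairs are dropped pairwise.
#'
#' @param x,y Paired values; x is the reference axis.
#' @param labels Length-2 character vector naming x and y.
#' @param iccForm Passed to [iccAbsolute()].
#' @return An [AgreementReport-class].
#' @export
agreementReport <- function(x, y, labels = c("x", "y"),
                            iccForm = c("ICC(2,1)", "ICC(3,1)")) {
    iccForm <- match.arg(iccForm)
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    reg <- linReg(x, y)
    new("AgreementReport", r = pearsonR(x, y), slope = reg$slope,
        intercept = reg$intercept, icc = iccAbsolute(x, y, iccForm),
        iccForm = iccForm, n = length(x), labels = labels)
}

#' @rdname AgreementReport-class
#' @param x An [AgreementReport-class].
#' @param ... Ignored.
#' @export
as.list.AgreementReport <- function(x, ...) {
    list(x_label = x@labels[1], y_label = x@labels[2], r = x@r,
         slope = x@slope, intercept = x@intercept, icc = x@icc,
         icc_form = x@iccForm, n = x@n)
}
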