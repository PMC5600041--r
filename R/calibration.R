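#' Fit the Tmax calibration constants p and q
#'
#' Least-squares fit of the linear relation
#' \deqn{Tmax_{ref} = TD + p \cdot MTT + q}
#' i.e. (p, q) minimize the sum of squared differences between
#' TD + p*MTT + q and the reference Tmax. Since TD enters with unit
#' coefficient, the closed form is the simple regression of
#' (Tmax_ref - TD) on MTT. The constants are specific to the reference
#' deconvolution algorithm. Non-finite triples are excluded pairwise and
#' counted.
#'
#' @param td,mtt Bayesian TD and MTT estimates (s), equal length >= 3.
#' @param tmaxRef Reference Tmax values (s), e.g. from bSVD.
#' @param reference Label recorded in the fit.
#' @return A [CalibrationFit-class].
#' @examples
#' fit <- fitPQ(td = c(0, 1, 2, 3), mtt = c(4, 6, 8, 10),
#'              tmaxRef = c(0, 1, 2, 3) + 0.5 * c(4, 6, 8, 10) + 1)
#' c(fit@p, fit@q)   # 0.5, 1
#' @export
fitPQ <- function(td, mtt, tmaxRef, reference = "reference") {
    if (length(td) != length(mtt) || length(td) != length(tmaxRef))
        stop("'td', 'mtt' and 'tmaxRef' must have equal length")
    ok <- is.finite(td) & is.finite(mtt) & is.finite(tmaxRef)
    nExcluded <- sum(!ok)
    td <- td[ok]; mtt <- mtt[ok]; tmaxRef <- tmaxRef[ok]
    if (length(td) < 3L) stop("need at least 3 complete points")
    if (stats::sd(mtt) == 0)
        stop("degenerate design: 'mtt' is constant, p is unidentifiable")
    co <- stats::coef(stats::lm((tmaxRef - td) ~ mtt))
    p <- unname(co[2L]); q <- unname(co[1L])
    res <- tmaxRef - (td + p * mtt + q)
    new("CalibrationFit", p = p, q = q, reference = reference,
        nPoints = length(td), nExcluded = as.integer(nExcluded),
        rmsResidual = sqrt(mean(res^2)))
}

#' Apply calibration constants to Bayesian TD and MTT
#'
#' Elementwise evaluation of Tmax(Bayesian) = TD + p*MTT + q. Negative
#' results are not clipped; a warning reports how many occurred.
#'
#' @param td,mtt Numeric vectors of equal length (s).
#' @param fit A [CalibrationFit-class], or a list with elements p and q.
#' @return Numeric vector of calibrated Tmax values (s).
#' @export
applyPQ <- function(td, mtt, fit) {
    if (length(td) != length(mtt))
        stop("'td' and 'mtt' must have equal length")
    if (is(fit, "CalibrationFit")) { p <- fit@p; q <- fit@q }
    else { p <- fit$p; q <- fit$q }
    out <- td + p * mtt + q
    nNeg <- sum(out < 0, na.rm = TRUE)
    if (nNeg > 0)
        warning(sprintf("%d calibrated Tmax value(s) are negative", nNeg))
    out
}

#' Calibrate a Bayesian map set against a reference Tmax map
#'
#' Convenience wrapper joining two [PerfusionMaps-class] objects on
#' (slice, tile), fitting (p, q) and filling the Bayesian maps' \code{tmax}
#' column with the calibrated values.
#'
#' @param bayesMaps Bayesian [PerfusionMaps-class] (td, mtt populated).
#' @param refMaps Reference [PerfusionMaps-class] (tmax populated), or a
#'   numeric vector of reference Tmax values in the same tile order.
#' @return List with elements \code{fit} (a [CalibrationFit-class]) and
#'   \code{maps} (the Bayesian maps with calibrated \code{tmax}).
#' @export
calibrateTmax <- function(bayesMaps, refMaps) {
    stopifnot(is(bayesMaps, "PerfusionMaps"))
    bt <- mapTable(bayesMaps)
    if (is(refMaps, "PerfusionMaps")) {
        rt <- mapTable(refMaps)
        key <- merge(bt[c("slice", "tile", "td", "mtt")],
                     rt[c("slice", "tile", "tmax")],
                     by = c("slice", "tile"), sort = FALSE)
        refTmax <- key$tmax[order(match(paste(key$slice, key$tile),
                                        paste(bt$slice, bt$tile)))]
        label <- methodLabel(refMaps)
    } else {
        if (length(refMaps) != nrow(bt))
            stop("reference Tmax length must match the Bayesian map table")
        refTmax <- as.numeric(refMaps)
        label <- "external"
    }
    fit <- fitPQ(bt$td, bt$mtt, refTmax, reference = label)
    bt$tmax <- applyPQ(bt$td, bt$mtt, fit)
    out <- bayesMaps
    out@table <- bt
    out@params$calibration <- list(p = fit@p, q = fit@q, reference = label)
    list(fit = fit, maps = out)
}
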