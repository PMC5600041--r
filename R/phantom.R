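#' Build a uniform acquisition time grid
#'
#' Endpoint-inclusive grid: a 60-s acquisition sampled every 2 s yields 31
#' time points at 0, 2, ..., 60 s.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param duration Total acquisition window in seconds (>= dt).
#' @return A [TimeGrid-class].
#' @examples
#' makeTimeGrid(2, 60)   # 31 samples
#' @export
makeTimeGrid <- function(dt, duration) {
    if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
        stop("'dt' must be a single positive number")
    if (!is.numeric(duration) || length(duration) != 1L ||
        !is.finite(duration) || duration < dt)
        stop("'duration' must be a single number >= dt")
    n <- floor(duration / dt) + 1L
    new("TimeGrid", dt = dt, times = (seq_len(n) - 1L) * dt)
}

#' Gamma-variate arterial input function
#'
#' Standard first-pass bolus model
#' \deqn{AIF(t) = A \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
#'       \exp\left(\alpha - \frac{t - t_0}{\beta}\right)}
#' for t > t0 and 0 before arrival. Parameterized so that the peak value is
#' exactly \code{amplitude}, attained at \code{t0 + alpha*beta}.
#'
#' @param grid A [TimeGrid-class].
#' @param t0 Bolus arrival time (s, >= 0).
#' @param alpha Shape parameter (> 0, unitless).
#' @param beta Scale parameter (s, > 0).
#' @param amplitude Peak concentration (> 0, arbitrary concentration units).
#' @return A [Curve-class] labelled \code{"aif"}.
#' @export
gammaVariateAif <- function(grid, t0 = 6, alpha = 3, beta = 3,
                            amplitude = 300) {
    stopifnot(is(grid, "TimeGrid"))
    if (alpha <= 0 || beta <= 0 || amplitude <= 0 || t0 < 0)
        stop("'alpha', 'beta', 'amplitude' must be > 0 and 't0' >= 0")
    v <- .gammaVariate(grid@times, t0, alpha, beta, amplitude)
    new("Curve", grid = grid, values = v, label = "aif")
}

.gammaVariate <- function(t, t0, alpha, beta, amplitude) {
    s <- t - t0
    v <- numeric(length(t))
    pos <- s > 0
    v[pos] <- amplitude * (s[pos] / (alpha * beta))^alpha *
        exp(alpha - s[pos] / beta)
    v
}

#' Pointwise tissue residue function
#'
#' The three canonical residue shapes, each with continuous-time integral
#' exactly MTT: exponential \eqn{e^{-t/MTT}}, linear
#' \eqn{\max(0, 1 - t/(2\,MTT))} (support 2*MTT), and box (1 on the
#' half-open interval [0, MTT), 0 after).
#'
#' @param shape \code{"exponential"}, \code{"linear"} or \code{"box"}.
#' @param mtt Mean transit time in seconds (> 0).
#' @param grid A [TimeGrid-class].
#' @return A [Curve-class] labelled \code{"residue"} with R(0) = 1,
#'   non-increasing.
#' @export
residueCurve <- function(shape, mtt, grid) {
    stopifnot(is(grid, "TimeGrid"))
    if (!is.numeric(mtt) || length(mtt) != 1L || mtt <= 0)
        stop("'mtt' must be a single positive number")
    shape <- match.arg(shape, c("exponential", "linear", "box"))
    t <- grid@times
    v <- switch(shape,
        exponential = exp(-t / mtt),
        linear = pmax(0, 1 - t / (2 * mtt)),
        box = as.numeric(t < mtt))
    new("Curve", grid = grid, values = v, label = "residue")
}

# Bin-averaged residue kernel: h[j] = (1/dt) * integral of R over
# [t_j, t_j + dt). Area-preserving discretization -- dt * sum(h) equals MTT
# exactly whenever the residue support fits in the window, for any shape and
# any MTT (pointwise sampling of a box residue at dt = 2 s would not).
.residueKernel <- function(shape, mtt, grid) {
    dt <- grid@dt
    a <- grid@times
    b <- a + dt
    switch(shape,
        exponential = (mtt / dt) * (exp(-a / mtt) - exp(-b / mtt)),
        box = pmax(0, pmin(b, mtt) - pmin(a, mtt)) / dt,
        linear = {
            bb <- pmin(b, 2 * mtt)
            aa <- pmin(a, 2 * mtt)
            ((bb - aa) - (bb^2 - aa^2) / (4 * mtt)) / dt
        },
        stop("unknown residue shape: ", shape))
}

# Causal discrete convolution of two sampled signals, truncated to the grid
# length, scaled by dt: out[i] = dt * sum_j x[i-j+1] h[j].
.convolveCausal <- function(x, h, dt) {
    n <- length(x)
    full <- stats::convolve(x, rev(h), type = "open")
    dt * full[seq_len(n)]
}

# Fractional right-shift by `shift` seconds via linear interpolation between
# the two straddling integer lags; zero-filled on the left. Exact for shifts
# that are integer multiples of dt.
.shiftCurve <- function(v, shift, dt) {
    if (shift == 0) return(v)
    if (shift < 0) stop("only non-negative shifts are supported")
    s <- shift / dt
    d <- floor(s)
    f <- s - d
    n <- length(v)
    lag1 <- c(rep(0, min(d, n)), v)[seq_len(n)]
    if (f == 0) return(lag1)
    lag2 <- c(rep(0, min(d + 1, n)), v)[seq_len(n)]
    (1 - f) * lag1 + f * lag2
}

# Internal oversampling factor of the forward model. Convolution and the TD
# shift are carried out at dt/20 (0.1 s for the standard 2-s acquisition),
# where the phantom's 0.5-s delays and the default Bayesian delay grid are
# exact sample shifts; working at the acquisition resolution instead would
# alias -- at dt = 2 s a linear-interpolation shift is a 2-tap kernel and so
# is any box residue of width <= 2*dt, making (TD, MTT) unidentifiable.
.OVERSAMPLE <- 20L

.fineTimes <- function(grid) {
    dtF <- grid@dt / .OVERSAMPLE
    seq(0, max(grid@times), by = dtF)
}

# The continuous-time AIF is defined as the linear interpolant of its
# acquisition-grid samples (the convention of a measured input function),
# zero outside the window.
.upsampleAif <- function(aifValues, grid) {
    stats::approx(grid@times, aifValues, xout = .fineTimes(grid),
                  rule = 2)$y
}

# Bin-averaged residue kernel on an arbitrary uniform grid.
.residueKernelAt <- function(shape, mtt, times, dt) {
    g <- new("TimeGrid", dt = dt, times = times)
    .residueKernel(shape, mtt, g)
}

# Noiseless tissue curve for unit amplitude (a = CBF in mL/g/s):
# m(t) = (AIF(. - TD) * R)(t), evaluated on the fine internal grid and
# sampled back at the acquisition times. Shared by the phantom generator and
# the Bayesian model basis, which must agree on the forward model.
.tissueModelFine <- function(aifFine, td, mtt, shape, grid) {
    dtF <- grid@dt / .OVERSAMPLE
    h <- .residueKernelAt(shape, mtt, .fineTimes(grid), dtF)
    b <- .convolveCausal(aifFine, h, dtF)
    .downsample(.shiftCurve(b, td, dtF))
}

.downsample <- function(vFine) {
    vFine[seq(1L, length(vFine), by = .OVERSAMPLE)]
}

.tissueModel <- function(aifValues, td, mtt, shape, grid) {
    .tissueModelFine(.upsampleAif(aifValues, grid), td, mtt, shape, grid)
}

#' Synthesize one tissue concentration curve
#'
#' Forward tracer-kinetic model: the tissue curve is the convolution of the
#' global AIF, arrival-delayed by TD, with the flow-scaled residue function,
#' \deqn{C(t) = \frac{CBV/100}{MTT}\,(AIF(\cdot - TD) \otimes R)(t),}
#' plus additive i.i.d. Gaussian noise. The convolution is evaluated on a
#' fine internal grid (dt/20, i.e. 0.1 s for the standard acquisition) with
#' the continuous AIF taken as the linear interpolant of its samples; the
#' arrival delay is a (sub-acquisition-sample) linear-interpolation shift at
#' that resolution, so TD need not be a multiple of dt; the residue enters
#' through its bin-averaged kernel so that tracer is conserved; the result
#' is sampled back at the acquisition times.
#'
#' @param aif The global AIF [Curve-class].
#' @param td Tracer arrival delay (s, >= 0).
#' @param mtt Mean transit time (s, > 0).
#' @param cbv Cerebral blood volume (mL/100g, > 0).
#' @param shape Residue shape (see [residueCurve()]).
#' @param noiseSd Gaussian noise standard deviation in concentration units.
#' @param seed Optional integer; when given the noise is reproducible.
#' @return A [Curve-class] labelled \code{"tissue"}.
#' @export
synthesizeTissueCurve <- function(aif, td, mtt, cbv, shape,
                                  noiseSd = 0, seed = NULL) {
    stopifnot(is(aif, "Curve"))
    if (td < 0 || mtt <= 0 || cbv <= 0 || noiseSd < 0)
        stop("need td >= 0, mtt > 0, cbv > 0, noiseSd >= 0")
    shape <- match.arg(shape, c("exponential", "linear", "box"))
    grid <- aif@grid
    amp <- (cbv / 100) / mtt                     # CBF in mL/g/s
    v <- amp * .tissueModel(aif@values, td, mtt, shape, grid)
    if (noiseSd > 0) {
        if (!is.null(seed)) set.seed(seed)
        v <- v + stats::rnorm(length(v), sd = noiseSd)
    }
    new("Curve", grid = grid, values = v, label = "tissue")
}

#' Phantom configuration
#'
#' Defaults reproduce the published digital phantom design: 7 tracer arrival
#' delays (0 to 3 s in 0.5-s steps) by 7 mean transit times (3.4, 4.0, 4.8,
#' 6.0, 8.0, 12.0, 24.0 s) of square tiles per tissue slice; 5 CBV levels
#' (1 to 5 mL/100g) crossed with 3 residue shapes across 15 tissue slices;
#' one extra slice carrying the global AIF and VOF (16 slices total);
#' sampling every 2 s over 60 s.
#'
#' @param tdLevels,mttLevels,cbvLevels,shapes Parameter sequences.
#' @param tileSize Voxels per tile edge (tiles are square). The default 8 is
#'   a desk-scale replica of the published phantom's roughly 32-voxel tiles.
#' @param dt,duration Acquisition sampling (s).
#' @param noiseSd Gaussian noise sd in concentration units, or \code{NULL}
#'   (default) for the built-in calibration: per-voxel peak tissue
#'   signal-to-noise ratio of 5 on the highest-contrast tile (CBV = 5,
#'   MTT = 3.4 s, exponential residue) at full scale (32-voxel tile edge),
#'   scaled by \code{tileSize/32} so that the tile-mean ROI curves — the
#'   unit every analysis operates on — carry the same noise level as the
#'   full-scale design regardless of the desk-scale tile size.
#' @param aifParams Named list \code{(t0, alpha, beta, amplitude)} for the
#'   gamma-variate global AIF. The default (arrival 6 s, alpha = 3,
#'   beta = 3 s, peak 300) emulates a measured global CT arterial input
#'   function of real bolus-tracking data, whose first pass is broadened by
#'   arterial dispersion (about 11 s full width at half maximum) — the same
#'   global-AIF convention under which tracer dispersion is folded into the
#'   tissue MTT.
#' @param vofDelay,vofGain VOF model: the VOF is a delayed, amplified copy of
#'   the AIF.
#' @param seed Integer RNG seed for the noise realization.
#' @return A validated configuration list of class \code{"PhantomConfig"}.
#' @export
phantomConfig <- function(tdLevels = seq(0, 3, by = 0.5),
                          mttLevels = c(3.4, 4.0, 4.8, 6.0, 8.0, 12.0, 24.0),
                          cbvLevels = seq(1, 5, by = 1),
                          shapes = c("exponential", "linear", "box"),
                          tileSize = 8L, dt = 2, duration = 60,
                          noiseSd = NULL,
                          aifParams = list(t0 = 6, alpha = 3, beta = 3,
                                           amplitude = 300),
                          vofDelay = 4, vofGain = 1.1, seed = 42L) {
    if (!length(tdLevels) || !length(mttLevels) || !length(cbvLevels) ||
        !length(shapes))
        stop("parameter level lists must be non-empty")
    if (any(tdLevels < 0) || any(mttLevels <= 0) || any(cbvLevels <= 0))
        stop("need tdLevels >= 0, mttLevels > 0, cbvLevels > 0")
    shapes <- vapply(shapes, match.arg,
                     c("exponential", "linear", "box"), FUN.VALUE = "")
    grid <- makeTimeGrid(dt, duration)
    if (is.null(noiseSd)) {
        aif <- do.call(gammaVariateAif, c(list(grid = grid), aifParams))
        ref <- synthesizeTissueCurve(aif, td = 0, mtt = min(mttLevels),
                                     cbv = max(cbvLevels),
                                     shape = "exponential")
        noiseSd <- max(ref@values) / 5 * tileSize / 32
    }
    cfg <- list(tdLevels = as.numeric(tdLevels),
                mttLevels = as.numeric(mttLevels),
                cbvLevels = as.numeric(cbvLevels),
                shapes = unname(shapes), tileSize = as.integer(tileSize),
                dt = dt, duration = duration, noiseSd = noiseSd,
                aifParams = aifParams, vofDelay = vofDelay,
                vofGain = vofGain, seed = as.integer(seed))
    class(cfg) <- "PhantomConfig"
    cfg
}

#' Build the digital perfusion phantom
#'
#' Generates the full 4-D volume: one tissue slice per (CBV, shape) pair,
#' each holding a |tdLevels| x |mttLevels| grid of square tiles whose voxels
#' are independent Gaussian-noise realizations of the tile's noiseless tissue
#' curve; a final slice embeds the noise-free global AIF (upper half) and VOF
#' (lower half). Ground truth (TD, MTT, CBV, CBF = 60*CBV/MTT, shape) is
#' attached per tile.
#'
#' @param config A [phantomConfig()] list.
#' @return A [PhantomVolume-class].
#' @examples
#' ph <- buildPhantom(phantomConfig(cbvLevels = 5, shapes = "exponential",
#'                                  tileSize = 2))
#' dim(phantomData(ph))
#' @export
buildPhantom <- function(config = phantomConfig()) {
    if (!inherits(config, "PhantomConfig"))
        config <- do.call(phantomConfig, config)
    grid <- makeTimeGrid(config$dt, config$duration)
    nT <- nSamples(grid)
    aif <- do.call(gammaVariateAif, c(list(grid = grid), config$aifParams))
    vof <- new("Curve", grid = grid,
               values = config$vofGain *
                   .shiftCurve(aif@values, config$vofDelay, grid@dt),
               label = "vof")

    nTd <- length(config$tdLevels); nMtt <- length(config$mttLevels)
    ts <- config$tileSize
    nRow <- nTd * ts; nCol <- nMtt * ts
    combos <- expand.grid(shape = config$shapes, cbv = config$cbvLevels,
                          stringsAsFactors = FALSE)  # shape varies fastest
    nTissue <- nrow(combos)
    data <- array(0, dim = c(nTissue + 1L, nRow, nCol, nT))

    # one fine-grid convolution per (shape, MTT); tiles then differ only by
    # the arrival-delay shift and the flow amplitude
    dtF <- grid@dt / .OVERSAMPLE
    aifFine <- .upsampleAif(aif@values, grid)
    tF <- .fineTimes(grid)
    baseFine <- list()
    for (sh in unique(config$shapes))
        for (m in config$mttLevels)
            baseFine[[paste(sh, m)]] <-
                .convolveCausal(aifFine, .residueKernelAt(sh, m, tF, dtF),
                                dtF)

    set.seed(config$seed)
    gt <- vector("list", nTissue)
    geom <- vector("list", nTissue)
    for (s in seq_len(nTissue)) {
        cbv <- combos$cbv[s]; shape <- combos$shape[s]
        gtRows <- vector("list", nTd * nMtt)
        geomRows <- vector("list", nTd * nMtt)
        for (i in seq_len(nTd)) for (j in seq_len(nMtt)) {
            td <- config$tdLevels[i]; mtt <- config$mttLevels[j]
            clean <- (cbv / 100) / mtt *
                .downsample(.shiftCurve(baseFine[[paste(shape, mtt)]],
                                        td, dtF))
            block <- matrix(rep(clean, each = ts * ts), nrow = ts * ts)
            if (config$noiseSd > 0)
                block <- block +
                    matrix(stats::rnorm(length(block), sd = config$noiseSd),
                           nrow = ts * ts)
            rows <- (i - 1L) * ts + seq_len(ts)
            cols <- (j - 1L) * ts + seq_len(ts)
            data[s, rows, cols, ] <- array(block, dim = c(ts, ts, nT))
            tile <- (i - 1L) * nMtt + j
            gtRows[[tile]] <- data.frame(slice = s, tile = tile, td = td,
                                         mtt = mtt, cbv = cbv,
                                         cbf = 60 * cbv / mtt, shape = shape)
            geomRows[[tile]] <- data.frame(slice = s, tile = tile,
                                           row0 = (i - 1L) * ts,
                                           col0 = (j - 1L) * ts, size = ts)
        }
        gt[[s]] <- do.call(rbind, gtRows)
        geom[[s]] <- do.call(rbind, geomRows)
    }
    # dedicated AIF/VOF slice: AIF in the upper half rows, VOF in the lower
    half <- nRow %/% 2L
    data[nTissue + 1L, seq_len(half), , ] <-
        rep(aif@values, each = half * nCol)
    data[nTissue + 1L, (half + 1L):nRow, , ] <-
        rep(vof@values, each = (nRow - half) * nCol)

    new("PhantomVolume", data = data, grid = grid,
        tileGeometry = do.call(rbind, geom), groundTruth = do.call(rbind, gt),
        aif = aif, vof = vof, config = unclass(config))
}
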