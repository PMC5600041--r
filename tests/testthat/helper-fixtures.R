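# Shared fixtures. Everything is generated in code; the expensive default
# study run is computed once per test session and reused by the acceptance
# blocks.

.fixtures <- new.env(parent = emptyenv())

defaultGrid <- function() makeTimeGrid(2, 60)

defaultAif <- function() gammaVariateAif(defaultGrid())

# a small noiseless phantom: one CBV level, all shapes, tiny tiles
smallNoiselessPhantom <- function() {
    if (is.null(.fixtures$smallNoiseless))
        .fixtures$smallNoiseless <- buildPhantom(
            phantomConfig(noiseSd = 0, cbvLevels = 3, tileSize = 2L))
    .fixtures$smallNoiseless
}

# the full default study: phantom (seed 42), bSVD reference, Bayesian maps,
# (p, q) calibration -- the run every acceptance statistic is computed from
defaultStudyRun <- function() {
    if (is.null(.fixtures$study)) {
        t0 <- Sys.time()
        phantom <- buildPhantom(phantomConfig(seed = 42L))
        .fixtures$phantomSeconds <-
            as.numeric(Sys.time() - t0, units = "secs")
        bsvd <- deconvolveVolume(phantom, "bsvd", threshold = 0.15)
        bayes <- bayesFitVolume(phantom)
        cal <- calibrateTmax(bayes, bsvd)
        .fixtures$study <- list(phantom = phantom, bsvd = bsvd,
                                bayes = cal$maps, fit = cal$fit)
    }
    .fixtures$study
}

# direct double-loop causal convolution, the independent forward oracle
directConvolve <- function(x, h, dt) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n))
        for (j in seq_len(i))
            out[i] <- out[i] + dt * x[i - j + 1] * h[j]
    out
}
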