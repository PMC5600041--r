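test_that("convolution systems have the documented structure", {
    g <- makeTimeGrid(1, 5)
    impulse <- new("Curve", grid = g, values = c(1, 0, 0, 0, 0, 0),
                   label = "aif")
    A <- buildConvolutionSystem(impulse, "causal")@matrix
    expect_equal(A, diag(6))
    aif <- gammaVariateAif(defaultGrid())
    Ac <- buildConvolutionSystem(aif, "causal")@matrix
    expect_true(all(Ac[upper.tri(Ac)] == 0))
    expect_equal(Ac[, 1], 2 * curveValues(aif))
    B <- buildConvolutionSystem(aif, "circulant")@matrix
    expect_equal(dim(B), c(62L, 62L))
    # row i is row 1 rotated right by i-1
    for (i in c(2L, 17L, 62L))
        expect_equal(B[i, ], B[1, ((seq_len(62) - i) %% 62) + 1])
    zero <- new("Curve", grid = g, values = numeric(6), label = "aif")
    expect_error(buildConvolutionSystem(zero), "zero")
})

test_that("bSVD recovers a known scaled residue from forward-synthesized data", {
    g <- defaultGrid()
    aif <- gammaVariateAif(g)
    for (sh in c("linear", "box")) {
        k0 <- (3 / 100) / 6 * curveValues(residueCurve(sh, 6, g))
        Cv <- directConvolve(curveValues(aif), k0, samplingInterval(g))
        ct <- new("Curve", grid = g, values = Cv, label = "tissue")
        est <- svdDeconvolve(ct, aif, "bsvd", threshold = 0.001)
        expect_lt(sqrt(mean((residueValues(est) - k0)^2)) / max(k0), 0.02)
    }
})

test_that("a one-sample delay of the tissue curve shifts the residue peak by one sample", {
    g <- defaultGrid()
    aif <- gammaVariateAif(g)
    k0 <- (3 / 100) / 6 * curveValues(residueCurve("exponential", 6, g))
    Cv <- directConvolve(curveValues(aif), k0, samplingInterval(g))
    ct0 <- new("Curve", grid = g, values = Cv, label = "tissue")
    ct1 <- new("Curve", grid = g, values = c(0, Cv[-length(Cv)]),
               label = "tissue")
    k0est <- residueValues(svdDeconvolve(ct0, aif, "bsvd", threshold = 0.05))
    k1est <- residueValues(svdDeconvolve(ct1, aif, "bsvd", threshold = 0.05))
    expect_equal(which.max(k1est), which.max(k0est) + 1L)
})

test_that("svdDeconvolve validates its arguments", {
    aif <- defaultAif()
    ct <- synthesizeTissueCurve(aif, 0, 6, 3, "exponential")
    expect_error(svdDeconvolve(ct, aif, threshold = 1), "threshold")
    other <- synthesizeTissueCurve(gammaVariateAif(makeTimeGrid(1, 30)),
                                   0, 6, 3, "exponential")
    expect_error(svdDeconvolve(other, aif), "grid")
})

test_that("Tmax extraction follows the argmax and refinement conventions", {
    g <- makeTimeGrid(2, 6)
    est <- new("ResidueEstimate", k = c(0, 0.2, 1.0, 0.5), grid = g,
               method = "bsvd", thresholdUsed = 0.15)
    ct <- new("Curve", grid = g, values = c(0, 1, 1, 1), label = "tissue")
    aif <- new("Curve", grid = g, values = c(1, 2, 1, 0), label = "aif")
    expect_equal(mapsFromResidue(est, ct, aif, refine = "none")$tmax, 4.0)
    # symmetric neighbours: every refinement stays at the centre sample
    sym <- new("ResidueEstimate", k = c(0.5, 1.0, 0.5, 0), grid = g,
               method = "bsvd", thresholdUsed = 0.15)
    expect_equal(mapsFromResidue(sym, ct, aif, refine = "parabolic")$tmax, 2.0)
    expect_equal(mapsFromResidue(sym, ct, aif, refine = "centroid")$tmax, 2.0)
    # ties resolve to the earliest time without refinement
    tie <- new("ResidueEstimate", k = c(0, 1, 1, 0), grid = g,
               method = "bsvd", thresholdUsed = 0.15)
    expect_equal(mapsFromResidue(tie, ct, aif, refine = "none")$tmax, 2.0)
    flat <- new("ResidueEstimate", k = c(0, 0, 0, 0), grid = g,
               method = "bsvd", thresholdUsed = 0.15)
    expect_warning(m <- mapsFromResidue(flat, ct, aif), "undefined")
    expect_true(all(is.na(m)))
})

test_that("noiseless box tiles return CBF near 60*CBV/MTT at fine truncation", {
    aif <- defaultAif()
    for (m in c(4, 8)) {
        ct <- synthesizeTissueCurve(aif, 0, m, 3, "box")
        est <- svdDeconvolve(ct, aif, "ssvd", threshold = 0.001)
        maps <- mapsFromResidue(est, ct, aif)
        expect_equal(maps$cbf, 60 * 3 / m, tolerance = 0.05)
        expect_equal(maps$cbv, 3, tolerance = 0.05)
        expect_equal(maps$mtt, m, tolerance = 0.1)
    }
})

test_that("reconvolving the accepted residue reproduces noiseless data", {
    g <- defaultGrid()
    aif <- gammaVariateAif(g)
    A <- buildConvolutionSystem(aif, "causal")@matrix
    k0 <- (3 / 100) / 6 * curveValues(residueCurve("linear", 6, g))
    Cv <- directConvolve(curveValues(aif), k0, samplingInterval(g))
    ct <- new("Curve", grid = g, values = Cv, label = "tissue")
    k <- residueValues(svdDeconvolve(ct, aif, "bsvd", threshold = 0.001))
    expect_lt(sqrt(sum((A %*% k - Cv)^2) / sum(Cv^2)), 0.02)
})

test_that("bSVD CBF tolerates delay where sSVD degrades", {
    aif <- defaultAif()
    cbfOf <- function(method, td) {
        ct <- synthesizeTissueCurve(aif, td, 6, 3, "exponential")
        mapsFromResidue(svdDeconvolve(ct, aif, method, 0.15), ct, aif)$cbf
    }
    bRel <- abs(cbfOf("bsvd", 2) - cbfOf("bsvd", 0)) / cbfOf("bsvd", 0)
    sRel <- abs(cbfOf("ssvd", 2) - cbfOf("ssvd", 0)) / cbfOf("ssvd", 0)
    expect_lt(bRel, 0.05)
    expect_lte(bRel, sRel)
})

test_that("noiseless tile Tmax is monotone in TD, and in MTT for exponential residues", {
    ph <- smallNoiselessPhantom()
    gt <- groundTruth(ph)
    tmax <- mapTable(deconvolveVolume(ph, "bsvd", threshold = 0.15))$tmax
    for (sh in unique(gt$shape))
        for (m in unique(gt$mtt)) {
            s <- gt$shape == sh & gt$mtt == m
            expect_true(all(diff(tmax[s][order(gt$td[s])]) >= -1e-9),
                        label = sprintf("TD-monotone (%s, MTT=%g)", sh, m))
        }
    for (td in unique(gt$td)) {
        s <- gt$shape == "exponential" & gt$td == td
        expect_true(all(diff(tmax[s][order(gt$mtt[s])]) >= -1e-9),
                    label = sprintf("MTT-monotone (TD=%g)", td))
    }
})

test_that("oSVD raises truncation until the residue is smooth", {
    aif <- defaultAif()
    ct <- synthesizeTissueCurve(aif, 1, 6, 3, "exponential", noiseSd = 0.5,
                                seed = 3L)
    est <- svdDeconvolve(ct, aif, "osvd", threshold = 0.05, oiLimit = 0.035)
    expect_gte(est@thresholdUsed, 0.05)
    expect_lte(BayesTmax:::.oscillationIndex(residueValues(est)), 0.035)
})

test_that("per-voxel and tile-mean deconvolution agree on noiseless data", {
    ph <- buildPhantom(phantomConfig(noiseSd = 0, cbvLevels = 3,
                                     shapes = "exponential", tileSize = 2L))
    a <- mapTable(deconvolveVolume(ph, "bsvd", roiMode = "tile_mean"))
    b <- mapTable(deconvolveVolume(ph, "bsvd", roiMode = "per_voxel"))
    expect_equal(a$tmax, b$tmax, tolerance = 1e-8)
    expect_equal(a$cbf, b$cbf, tolerance = 1e-8)
})
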