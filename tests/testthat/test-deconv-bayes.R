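test_that("search specs are validated and hold the phantom ranges", {
    spec <- bayesSearchSpec()
    expect_true(min(spec$tdGrid) <= 0 && max(spec$tdGrid) >= 3)
    expect_true(min(spec$mttGrid) <= 3.4 && max(spec$mttGrid) >= 24)
    expect_error(bayesSearchSpec(tdGrid = numeric()), "non-empty")
    expect_error(bayesSearchSpec(tdGrid = c(1, 0.5)), "sorted")
    expect_error(bayesSearchSpec(mttGrid = c(-1, 2)), "mttGrid > 0")
})

test_that("noiseless curves are recovered to grid resolution", {
    aif <- defaultAif()
    spec <- bayesSearchSpec()
    ct <- synthesizeTissueCurve(aif, td = 2, mtt = 8, cbv = 3,
                                shape = "exponential")
    est <- bayesFitCurve(ct, aif, spec)
    expect_equal(est@td, 2, tolerance = 0.1 / 2)
    mttStep <- max(diff(spec$mttGrid[spec$mttGrid <= 9]))
    expect_lt(abs(est@mtt - 8), mttStep)
    expect_identical(est@shape, "exponential")
    expect_equal(est@cbf, 60 * 3 / 8, tolerance = 0.02)
    expect_false(est@lowConfidence)
})

test_that("profiled amplitude equals the one-regressor least-squares coefficient", {
    aif <- defaultAif()
    m <- BayesTmax:::.tissueModel(curveValues(aif), td = 1.5, mtt = 6,
                                  shape = "linear", aif@grid)
    set.seed(4)
    y <- 0.007 * m + rnorm(length(m), sd = 0.1)
    aStar <- sum(y * m) / sum(m * m)
    expect_equal(aStar, unname(coef(lm(y ~ 0 + m))), tolerance = 1e-12)
})

test_that("an exact multiple of a grid model is found with zero residual", {
    aif <- defaultAif()
    spec <- bayesSearchSpec(tdGrid = seq(0, 3, 0.5),
                            mttGrid = c(3, 6, 12, 24),
                            summary = "map")
    m <- BayesTmax:::.tissueModel(curveValues(aif), td = 1.5, mtt = 6,
                                  shape = "box", aif@grid)
    ct <- new("Curve", grid = aif@grid, values = 0.004 * m, label = "tissue")
    est <- bayesFitCurve(ct, aif, spec)
    expect_identical(est@td, 1.5)
    expect_identical(est@mtt, 6)
    expect_identical(est@shape, "box")
    expect_equal(est@cbf, 6000 * 0.004, tolerance = 1e-8)
    expect_lt(est@rss, 1e-10 * sum(curveValues(ct)^2))
})

test_that("the grid posterior is normalized", {
    aif <- defaultAif()
    ct <- synthesizeTissueCurve(aif, 1, 6, 3, "exponential", noiseSd = 0.3,
                                seed = 5L)
    est <- bayesFitCurve(ct, aif, bayesSearchSpec(), details = TRUE)
    post <- attr(est, "posterior")
    expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
    expect_true(all(post$posterior >= 0))
})

test_that("a flat curve is flagged low-confidence but still summarized", {
    aif <- defaultAif()
    set.seed(6)
    ct <- new("Curve", grid = aif@grid,
              values = rnorm(nSamples(aif@grid), sd = 0.05),
              label = "tissue")
    est <- bayesFitCurve(ct, aif)
    expect_true(est@lowConfidence)
    expect_true(is.finite(est@td) && is.finite(est@mtt))
})

test_that("noiseless exponential tiles recover TD everywhere and shapes are identified", {
    ph <- smallNoiselessPhantom()
    gt <- groundTruth(ph)
    maps <- mapTable(bayesFitVolume(ph))
    exps <- gt$shape == "exponential"
    expect_lt(max(abs(maps$td[exps] - gt$td[exps])), 0.1 + 1e-9)
    # generating shape wins the evidence on tiles resolvable at dt = 2 s
    res <- gt$mtt >= 2 * samplingInterval(phantomAif(ph))
    expect_gte(mean(maps$shape[res] == gt$shape[res]), 0.95)
})

test_that("tile-mean and per-voxel fits coincide on noiseless data", {
    ph <- buildPhantom(phantomConfig(noiseSd = 0, cbvLevels = 2,
                                     shapes = "linear", tileSize = 2L))
    spec <- bayesSearchSpec(tdGrid = seq(0, 3.5, 0.25),
                            mttGrid = exp(seq(log(2), log(30),
                                              length.out = 25)))
    a <- mapTable(bayesFitVolume(ph, spec, roiMode = "tile_mean"))
    b <- mapTable(bayesFitVolume(ph, spec, roiMode = "per_voxel"))
    expect_equal(a$td, b$td, tolerance = 1e-9)
    expect_equal(a$mtt, b$mtt, tolerance = 1e-9)
})

test_that("estimates degrade continuously, not catastrophically, as noise doubles", {
    ph1 <- buildPhantom(phantomConfig(seed = 7L))
    g <- groundTruth(ph1)
    sd1 <- ph1@config$noiseSd
    ph2 <- buildPhantom(phantomConfig(noiseSd = 2 * sd1, seed = 8L))
    b1 <- mapTable(bayesFitVolume(ph1))
    b2 <- mapTable(bayesFitVolume(ph2))
    s <- g$cbv >= 3   # ROI-level SNR >= ~15: the informative regime
    r1 <- cor(g$td[s], b1$td[s], method = "spearman")
    r2 <- cor(g$td[s], b2$td[s], method = "spearman")
    expect_gte(r1, 0.95)
    expect_gte(r2, 0.95)
    m1 <- cor(g$mtt[s], b1$mtt[s], method = "spearman")
    m2 <- cor(g$mtt[s], b2$mtt[s], method = "spearman")
    expect_gte(m1, 0.9)
    expect_gt(m2, m1 - 0.05)
})
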