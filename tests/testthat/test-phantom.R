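test_that("time grids are endpoint-inclusive and validated", {
    g <- makeTimeGrid(2, 60)
    expect_equal(nSamples(g), 31L)
    expect_equal(timePoints(g), seq(0, 60, by = 2))
    expect_equal(nSamples(makeTimeGrid(1, 10)), 11L)
    expect_error(makeTimeGrid(0, 60), "dt")
    expect_error(makeTimeGrid(2, 1), "duration")
})

test_that("gamma-variate AIF is causal, non-negative, and peaks at its mode", {
    fine <- makeTimeGrid(0.01, 60)
    aif <- gammaVariateAif(fine, t0 = 6, alpha = 3, beta = 1.5,
                           amplitude = 300)
    v <- curveValues(aif)
    expect_true(all(v[timePoints(fine) <= 6] == 0))
    expect_true(all(v >= 0))
    # analytic mode at t0 + alpha*beta, peak value = amplitude
    expect_equal(timePoints(fine)[which.max(v)], 6 + 3 * 1.5,
                 tolerance = 1e-3)
    expect_equal(max(v), 300, tolerance = 1e-4)
    expect_error(gammaVariateAif(fine, alpha = -1), "alpha")
})

test_that("residue curves start at 1, never increase, and integrate to MTT", {
    g <- defaultGrid()
    for (sh in c("exponential", "linear", "box"))
        for (m in c(3.4, 4.0, 4.8, 6.0, 8.0, 12.0, 24.0)) {
            r <- residueCurve(sh, m, g)
            v <- curveValues(r)
            expect_identical(v[1], 1)
            expect_true(all(diff(v) <= 0))
        }
    # fine-grid quadrature: integral of R equals MTT within 0.1%
    fine <- makeTimeGrid(0.001, 60)
    tf <- timePoints(fine)
    for (sh in c("exponential", "linear", "box"))
        for (m in c(3.4, 6.0, 12.0)) {
            v <- curveValues(residueCurve(sh, m, fine))
            integral <- sum(diff(tf) * (v[-1] + v[-length(v)]) / 2)
            # exponential carries an exp(-60/m) analytic tail past the window
            tail <- if (sh == "exponential") m * exp(-60 / m) else 0
            expect_equal(integral + tail, m, tolerance = 1e-3)
        }
    # half-open box convention
    expect_equal(curveValues(residueCurve("box", 4, g))[1:4], c(1, 1, 0, 0))
    expect_error(residueCurve("gamma", 4, g))
})

test_that("tissue synthesis conserves tracer on a window that holds the bolus", {
    g <- makeTimeGrid(2, 240)
    aif <- gammaVariateAif(g)
    trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
    aArea <- trapz(timePoints(g), curveValues(aif))
    for (sh in c("exponential", "linear", "box"))
        for (m in c(3.4, 8, 24))
            for (td in c(0, 1.5, 3)) {
                ct <- synthesizeTissueCurve(aif, td, m, cbv = 2, shape = sh)
                ratio <- trapz(timePoints(g), curveValues(ct)) / aArea
                expect_equal(ratio, 2 / 100, tolerance = 0.01)
            }
})

test_that("box-shape tissue curve matches a direct moving-integral oracle", {
    g <- defaultGrid()
    aif <- gammaVariateAif(g)
    mtt <- 4; cbv <- 3
    ct <- synthesizeTissueCurve(aif, td = 0, mtt = mtt, cbv = cbv,
                                shape = "box")
    # independent oracle: Riemann sum of the MTT-length moving integral of
    # the linearly interpolated AIF, scaled by (CBV/100)/MTT
    dtF <- 0.001
    tF <- seq(0, 60, by = dtF)
    aF <- approx(timePoints(g), curveValues(aif), xout = tF, rule = 2)$y
    oracle <- vapply(timePoints(g), function(t) {
        win <- tF > t - mtt & tF <= t
        (cbv / 100) / mtt * sum(aF[win]) * dtF
    }, 0)
    expect_equal(curveValues(ct), oracle, tolerance = 0.01)
})

test_that("tissue noise is reproducible under a seed", {
    aif <- defaultAif()
    c1 <- synthesizeTissueCurve(aif, 1, 6, 3, "exponential", noiseSd = 1,
                                seed = 11L)
    c2 <- synthesizeTissueCurve(aif, 1, 6, 3, "exponential", noiseSd = 1,
                                seed = 11L)
    expect_identical(curveValues(c1), curveValues(c2))
    expect_error(synthesizeTissueCurve(aif, -1, 6, 3, "exponential"), "td")
})

test_that("the default phantom reproduces the published grid design", {
    cfg <- phantomConfig()
    expect_equal(cfg$tdLevels, seq(0, 3, by = 0.5))
    expect_equal(cfg$mttLevels, c(3.4, 4.0, 4.8, 6.0, 8.0, 12.0, 24.0))
    expect_equal(cfg$cbvLevels, 1:5)
    expect_length(cfg$shapes, 3L)
    ph <- smallNoiselessPhantom()   # 1 CBV x 3 shapes
    expect_equal(dim(phantomData(ph))[1], 3 + 1)   # tissue slices + AIF/VOF
    expect_equal(nrow(groundTruth(ph)), 3 * 49)
    expect_equal(max(tileGeometry(ph)$tile), 49)
    # tile (i, j) carries TD = tdLevels[i], MTT = mttLevels[j]
    gt <- groundTruth(ph)
    expect_equal(gt$td[gt$slice == 1], rep(seq(0, 3, 0.5), each = 7))
    expect_equal(gt$mtt[gt$slice == 1],
                 rep(c(3.4, 4.0, 4.8, 6.0, 8.0, 12.0, 24.0), times = 7))
    expect_equal(gt$cbf, 60 * gt$cbv / gt$mtt)
    expect_error(buildPhantom(phantomConfig(cbvLevels = numeric())),
                 "non-empty")
})

test_that("noiseless tiles are spatially uniform and noisy builds are seeded", {
    ph <- smallNoiselessPhantom()
    d <- phantomData(ph)
    g <- tileGeometry(ph)[5, ]
    block <- d[g$slice, g$row0 + seq_len(g$size), g$col0 + seq_len(g$size), ]
    expect_equal(max(apply(block, 3, function(m) diff(range(m)))), 0)
    cfg <- phantomConfig(cbvLevels = 2, shapes = "exponential", tileSize = 2L,
                         seed = 99L)
    expect_identical(phantomData(buildPhantom(cfg)),
                     phantomData(buildPhantom(cfg)))
})

test_that("the AIF/VOF slice carries the stored global curves", {
    ph <- smallNoiselessPhantom()
    d <- phantomData(ph)
    s <- dim(d)[1]
    expect_equal(d[s, 1, 1, ], curveValues(phantomAif(ph)))
    expect_equal(d[s, dim(d)[2], 1, ], curveValues(phantomVof(ph)))
    # VOF is a delayed, amplified copy of the AIF
    expect_gt(which.max(curveValues(phantomVof(ph))),
              which.max(curveValues(phantomAif(ph))))
})
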