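test_that("true multi-stability is detected from same-support divergence", {
    x <- SteadyStateSamples(rbind(c(1, 2, 0), c(2, 1, 0)))
    ms <- detectMultistability(x)
    expect_true(ms$multistable)
    expect_identical(ms$groups[[1]], c(1L, 2L))
    # distinct supports: nothing to flag
    x2 <- SteadyStateSamples(rbind(c(1, 2, 0), c(2, 1, 1)))
    expect_false(detectMultistability(x2)$multistable)
    # within-tolerance replicates are not multi-stability
    x3 <- SteadyStateSamples(rbind(c(1, 2, 0), c(1.0000001, 2, 0)))
    expect_false(detectMultistability(x3, tol = 1e-3)$multistable)
    xMix <- SteadyStateSamples(rbind(c(1, 2, 0), c(2, 1, 0), c(1, 1, 0.5)))
    expect_error(inferSignMatrix(xMix, method = "bruteforce"),
                 "multi-stability")
})

test_that("compositionality guard flags unit-sum tables only", {
    rel <- SteadyStateSamples(rbind(c(0.2, 0.8), c(0.5, 0.5), c(0.9, 0.1)))
    expect_true(compositionalityCheck(rel))
    abs <- SteadyStateSamples(rbind(c(1, 2), c(2, 5)))
    expect_false(compositionalityCheck(abs))
    one <- SteadyStateSamples(rbind(c(1, 2)))
    expect_warning(res <- compositionalityCheck(one), "undecidable")
    expect_false(res)
})

test_that("relative yield follows its defining formula and antisymmetry", {
    x <- SteadyStateSamples(rbind(c(1, 0), c(3, 2)),
                            zeroTol = 1e-8)
    expect_equal(relativeYield(x, 1, 2), 0.5)        # (3-1)/(3+1)
    xEq <- SteadyStateSamples(rbind(c(2, 0), c(2, 1)))
    expect_equal(relativeYield(xEq, 1, 2), 0)
    xDown <- SteadyStateSamples(rbind(c(3, 0), c(1, 1)))
    expect_equal(relativeYield(xDown, 1, 2), -0.5)
    # swapping the two abundances flips the sign
    expect_equal(relativeYield(x, 1, 2), -local({
        sw <- SteadyStateSamples(rbind(c(3, 0), c(1, 2)))
        relativeYield(sw, 1, 2)
    }))
    expect_error(relativeYield(SteadyStateSamples(rbind(c(1, 0))), 1, 2),
                 "missing")
})

test_that("invasion responses are read off the invader's sign column", {
    s <- rbind(c(-1L, 1L), c(0L, -1L))
    expect_identical(predictInvasionResponse(s, 2)[1], "increase")
    s0 <- rbind(c(-1L, 0L), c(0L, -1L))
    expect_identical(predictInvasionResponse(s0, 2)[1], "no-change")
    sNA <- rbind(c(-1L, NA), c(0L, -1L))
    expect_identical(predictInvasionResponse(sNA, 2)[1], "unpredictable")
})

test_that("sign accuracy decomposes correct, false and undetermined", {
    truth <- matrix(sample(c(-1L, 0L, 1L), 64, replace = TRUE), 8, 8)
    expect_equal(signAccuracy(truth, truth)$accuracy, 100)
    # 50 correct, 10 false, 4 undetermined out of 64 entries
    inferred <- truth
    flip <- seq_len(10)
    inferred[flip] <- ifelse(truth[flip] == 0L, 1L, 0L)
    inferred[11:14] <- NA
    acc <- signAccuracy(inferred, truth)
    expect_equal(acc$accuracy, 100 * 50 / 64, tolerance = 1e-12)  # 78.125
    expect_equal(acc$undetermined, 4)
    det <- signAccuracy(inferred, truth, denominator = "determined")
    expect_equal(det$accuracy, 100 * 50 / 60, tolerance = 1e-12)
    allNA <- matrix(NA_integer_, 8, 8)
    expect_equal(signAccuracy(allNA, truth)$n_determined, 0)
    expect_error(signAccuracy(truth[1:4, ], truth), "shape")
})

test_that("robustness percentages are 100 at zero noise and bounded", {
    mod <- threeTaxonGLV()
    xs <- allSupportSamples(mod)
    set.seed(30)
    rb <- robustnessAnalysis(xs, etaGrid = c(0, 0.2), reps = 4)
    expect_true(all(rb$unchanged[["0"]] == 100))
    expect_true(all(rb$unchanged[["0.2"]] >= 0 &
                    rb$unchanged[["0.2"]] <= 100))
    expect_error(robustnessAnalysis(xs, 0, reps = 1), "reps")
})

test_that("interaction FDR counts truly-zero selections among discoveries", {
    trueA <- rbind(c(-1, 0.5, 0), c(0, -1, 0), c(0.2, 0, -1))
    inf <- rbind(c(-1, 0.4, 0.1), c(0, -1, 0), c(0.3, 0, -1))
    expect_equal(interactionFDR(inf, trueA), 1 / 3)
    expect_equal(interactionFDR(matrix(0, 3, 3), trueA), 0)
})

test_that("a trivial accuracy target needs almost no samples", {
    set.seed(31)
    ms <- minSampleSize(6, accuracyTarget = 1, reps = 2, omegaCap = 3)
    expect_lte(ms$omegaStar[["6"]], 4)
})
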