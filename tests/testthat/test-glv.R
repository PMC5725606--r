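test_that("noiseless GLV samples lie exactly on per-taxon hyperplanes", {
    set.seed(20)
    mod <- randomNetwork(6, connectivity = 0.5)
    x <- generateSampleSet(mod, omega = 30, presence = "uniform",
                           strict = FALSE)
    # hyperplane identity a_i . x + r_i = 0 for every sample containing i
    a <- abundances(x)
    for (i in 1:6) {
        Xi <- samplesWithTaxon(x, i)
        expect_true(all(abs(Xi %*% mod@A[i, ] + mod@r[i]) < 1e-8))
    }
    cons <- glvConsistency(x, 1)
    expect_gt(cons$r_squared, 1 - 1e-9)
})

test_that("saturating dynamics break the hyperplane alignment (low R^2)", {
    set.seed(21)
    mod <- randomNetwork(3, connectivity = 1, kind = "holling2", c = 1)
    x <- generateSampleSet(mod, omega = 7, presence = "uniform",
                           strict = FALSE, maxDraws = 5000)
    skip_if(nSamples(x) < 5, "too few feasible supports for this draw")
    r2 <- vapply(1:3, function(i) glvConsistency(x, i)$r_squared, numeric(1))
    expect_true(any(r2 < 1 - 1e-6))
})

test_that("exact row fit recovers the toy interaction and growth rate", {
    mod <- toyGLV()
    xs <- SteadyStateSamples(rbind(c(1, 0), steadyState(mod, c(1, 2))))
    f <- fitRowExact(xs, 1, aii = -1)
    expect_equal(f$a, c(-1, 0.5), tolerance = 1e-10)
    expect_equal(estimateGrowthRate(f$a, xs, 1), 1, tolerance = 1e-10)
    # zero row of interactions gives growth rate 0
    expect_equal(estimateGrowthRate(c(0, 0), xs, 1), 0)
})

test_that("diagonal communities yield zero off-diagonal estimates", {
    mod <- communityModel(A = diag(c(-1, -0.5, -2)), r = c(1, 0.6, 0.8))
    xs <- allSupportSamples(mod)
    for (i in 1:3) {
        f <- fitRowExact(xs, i, aii = diag(mod@A)[i])
        expect_equal(f$a[-i], c(0, 0), tolerance = 1e-10)
    }
})

test_that("noiseless exact recovery is machine-precise at moderate size", {
    set.seed(22)
    mod <- randomNetwork(12, connectivity = 0.4)
    x <- generateSampleSet(mod, omega = 120, presence = "uniform",
                           strict = FALSE)
    fit <- suppressWarnings(inferGLV(x, method = "exact", aii = -1))
    expect_lt(max(abs(interactionMatrix(fit) - mod@A)), 1e-6)
    expect_lt(max(abs(growthRates(fit) - mod@r)), 1e-6)
    expect_equal(glvNRMSE(fit, mod@A, mod@r)$nrmse_all, 0, tolerance = 1e-8)
})

test_that("unpenalized Lasso limit matches the exact hyperplane fit", {
    set.seed(23)
    mod <- randomNetwork(6, connectivity = 0.5)
    x <- generateSampleSet(mod, omega = 30, presence = "uniform",
                           strict = FALSE)
    ex <- fitRowExact(x, 2, aii = -1)
    la <- lassoInferRow(x, 2, aii = -1, lambda = 0)
    expect_equal(la$a, ex$a, tolerance = 1e-6)
})

test_that("half-normal diagonal draws are strictly negative near -1", {
    set.seed(24)
    d <- drawAii(5000)
    expect_true(all(d < 0))
    expect_equal(mean(d), -1, tolerance = 0.02)
    expect_equal(sd(d), 0.1, tolerance = 0.02)
})

test_that("knockoff copies preserve the fixed-X Gram structure", {
    set.seed(25)
    n <- 60; p <- 15
    X <- matrix(rnorm(n * p), n, p)
    X <- scale(X, center = TRUE, scale = FALSE)
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
    kn <- steadynet:::knockoffConstruct(X)
    G <- crossprod(X)
    expect_equal(crossprod(kn$Xk), G, tolerance = 1e-8)
    offdiagSame <- crossprod(X, kn$Xk) - (G - diag(kn$s))
    expect_lt(max(abs(offdiagSame)), 1e-8)
})

test_that("knockoff filter validates q and keeps null rows mostly empty", {
    x <- twoTaxonSamples()
    expect_error(knockoffFilterRow(x, 1, q = 1), "between 0 and 1")
    set.seed(26)
    mod <- communityModel(A = diag(rep(-1, 8)), r = runif(8, 0.5, 1))
    xs <- generateSampleSet(mod, omega = 60, presence = "uniform",
                            strict = FALSE)
    xn <- addNoise(xs, 0.1)
    nonEmpty <- 0
    for (i in 1:8) {
        res <- suppressWarnings(knockoffFilterRow(xn, i, q = 0.2, aii = -1))
        nonEmpty <- nonEmpty + (length(res$selected) > 0)
    }
    # each null row stays empty with probability >= 1 - q
    expect_lte(nonEmpty, 4)
})

test_that("orchestrated inference reports per-row diagnostics", {
    set.seed(27)
    mod <- randomNetwork(6, connectivity = 0.5)
    x <- generateSampleSet(mod, omega = 30, presence = "uniform",
                           strict = FALSE)
    fit <- suppressWarnings(inferGLV(x, method = "exact", aii = -1))
    d <- rowDiagnostics(fit)
    expect_equal(nrow(d), 6L)
    expect_true(all(d$glv_consistent, na.rm = TRUE))
    expect_error(inferGLV(x, method = "exact", aii = 1), "negative")
})

test_that("samples needed for perfect noiseless recovery scale with size", {
    omegaStarExact <- function(N, seed) {
        set.seed(seed)
        mod <- randomNetwork(N, connectivity = 0.4)
        for (omega in unique(ceiling(c(1, 2, 3, 4, 5, 6, 8) * N))) {
            set.seed(seed + omega)
            x <- tryCatch(generateSampleSet(mod, omega = omega,
                                            presence = "uniform",
                                            strict = FALSE),
                          error = function(e) NULL)
            if (is.null(x)) next
            fit <- suppressWarnings(inferGLV(x, method = "exact", aii = -1))
            if (isTRUE(max(abs(interactionMatrix(fit) - mod@A)) < 1e-6) &&
                isTRUE(max(abs(growthRates(fit) - mod@r)) < 1e-6))
                return(omega)
        }
        Inf
    }
    stars <- vapply(c(10, 20, 30), omegaStarExact, numeric(1), seed = 2609)
    expect_true(all(is.finite(stars)))
    expect_true(all(diff(stars) >= 0))       # grows with community size
    expect_lte(max(stars / c(10, 20, 30)), 8)  # and only linearly so
})
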