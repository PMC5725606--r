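test_that("random networks match the requested connectivity and diagonal", {
    set.seed(10)
    mod <- randomNetwork(50, connectivity = 0.4)
    expect_true(all(diag(mod@A) == -1))
    off <- mod@A[row(mod@A) != col(mod@A)]
    frac <- mean(off != 0)
    expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / length(off)))
    dense <- randomNetwork(10, connectivity = 1)
    expect_true(all(dense@A[row(dense@A) != col(dense@A)] != 0))
    expect_error(randomNetwork(10, connectivity = 0), "connectivity")
    set.seed(42); m1 <- randomNetwork(8, 0.4)
    set.seed(42); m2 <- randomNetwork(8, 0.4)
    expect_identical(m1@A, m2@A)
})

test_that("GLV steady states solve the restricted linear system", {
    mod <- toyGLV()
    expect_equal(steadyState(mod, c(1, 2)), c(1.2, 0.4), tolerance = 1e-12)
    expect_equal(steadyState(mod, 1), c(1, 0))        # r1 / (-a11)
    bad <- communityModel(A = rbind(c(-1, 0), c(0, -1)), r = c(-0.5, 1))
    expect_null(steadyState(bad, 1))                  # negative abundance
})

test_that("numerical integration agrees with the closed-form GLV solve", {
    set.seed(12)
    mod <- randomNetwork(5, connectivity = 0.5)
    supp <- c(1, 3, 4)
    direct <- steadyState(mod, supp)
    skip_if(is.null(direct), "support infeasible for this draw")
    integ <- integrateToSteadyState(mod, supp)
    expect_equal(integ, direct, tolerance = 1e-6)
})

test_that("initially absent taxa never re-appear during integration", {
    set.seed(13)
    mod <- randomNetwork(4, connectivity = 0.6, kind = "holling2")
    x <- integrateToSteadyState(mod, c(1, 2))
    skip_if(is.null(x), "support did not converge for this draw")
    expect_identical(x[c(3, 4)], c(0, 0))
})

test_that("every generated sample is a steady state of its dynamics", {
    set.seed(14)
    for (kind in c("glv", "holling2", "db", "cm")) {
        mod <- randomNetwork(5, connectivity = 0.4, kind = kind)
        x <- generateSampleSet(mod, omega = 8, presence = "uniform",
                               strict = FALSE)
        a <- abundances(x)
        for (s in seq_len(nrow(a)))
            expect_lt(max(abs(steadynet:::communityRHS(mod, a[s, ]))), 1e-8)
        # supports recorded by thresholding match the generated collections
        supp <- sampleSupports(x)
        for (s in seq_len(nrow(a)))
            expect_identical(supp[[s]], which(a[s, ] > 0))
    }
})

test_that("saturating models keep a constant Jacobian sign-pattern", {
    set.seed(15)
    for (kind in c("holling2", "db", "cm")) {
        mod <- randomNetwork(5, connectivity = 0.5, kind = kind)
        truth <- jacobianSignTruth(mod)
        off <- row(truth) != col(truth)
        for (k in 1:100) {
            state <- runif(5, 0.05, 2)
            J <- numericJacobian(mod, state)
            expect_identical(sign(J)[off], sign(truth)[off])
            expect_true(all(diag(J) < 0))
        }
    }
})

test_that("the GLV Jacobian sign oracle is the sign of A itself", {
    mod <- threeTaxonGLV()
    expect_identical(jacobianSignTruth(mod),
                     matrix(as.integer(sign(mod@A)), 3, 3))
})

test_that("multiplicative uniform noise respects its bounds and zeros", {
    x <- SteadyStateSamples(rbind(c(2, 0, 1), c(1, 3, 0)))
    expect_identical(abundances(addNoise(x, 0)), abundances(x))
    set.seed(16)
    for (k in 1:20) {
        pert <- abundances(addNoise(x, 0.5))
        expect_true(all(pert[abundances(x) == 0] == 0))
        expect_true(all(pert >= 0.5 * abundances(x) - 1e-12))
        expect_true(all(pert <= 1.5 * abundances(x) + 1e-12))
    }
    # symmetric noise: means recover the original values
    set.seed(17)
    acc <- Reduce(`+`, lapply(1:400, function(k) abundances(addNoise(x, 1))))
    expect_equal(acc / 400, abundances(x), tolerance = 0.15)
})

test_that("sample generation rejects duplicate supports and respects budgets", {
    set.seed(18)
    mod <- randomNetwork(4, connectivity = 0.3)
    expect_error(generateSampleSet(mod, omega = 16), "2\\^N")
    x <- generateSampleSet(mod, omega = 10, strict = FALSE)
    keys <- vapply(sampleSupports(x), paste, character(1), collapse = ",")
    expect_identical(anyDuplicated(keys), 0L)
    # heterogeneous presence re-draws the same common-taxon supports more often
    set.seed(19)
    rejU <- rejH <- 0
    for (k in 1:5) {
        m <- randomNetwork(6, connectivity = 0.3)
        xu <- generateSampleSet(m, omega = 15, presence = "uniform",
                                strict = FALSE)
        xh <- generateSampleSet(m, omega = 15, presence = "heterogeneous",
                                strict = FALSE)
        rejU <- rejU + attr(xu, "rejections")["duplicate"]
        rejH <- rejH + attr(xh, "rejections")["duplicate"]
    }
    expect_gt(rejH, rejU)
})

test_that("sample containers validate their invariants", {
    expect_error(SteadyStateSamples(rbind(c(-1, 2), c(1, 1))), "non-negative")
    expect_error(SteadyStateSamples(rbind(c(1), c(2))), "two taxa")
    x <- SteadyStateSamples(rbind(c(1, 0), c(1, 0), c(2, 1)))
    avg <- averageReplicates(x)
    expect_equal(nSamples(avg), 2L)
    expect_equal(unname(abundances(avg)[1, ]), c(1, 0))
})
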