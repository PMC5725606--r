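test_that("signOf thresholds entries at the tolerance", {
    expect_identical(signOf(c(0, 0), tol = 0), c(0L, 0L))
    expect_identical(signOf(c(1.0, -2.0, 0.0), tol = 1e-9), c(1L, -1L, 0L))
    expect_identical(signOf(c(1e-12, -1.0), tol = 1e-9), c(0L, -1L))
    expect_error(signOf(c(1, 2), tol = -1))
})

test_that("sign-satisfaction matches its combinatorial characterization", {
    expect_true(signSatisfies(c(0L, 0L), c(3, -7)))     # y = 0 works
    expect_true(signSatisfies(c(1L, 1L), c(1, -1)))     # y = (1, 1)
    expect_false(signSatisfies(c(1L, 1L), c(1, 1)))     # positives cannot cancel
    expect_true(signSatisfies(c(-1L, 1L), c(1, 1)))     # balanced signs
    # disjoint supports: constrained entries of w vanish
    expect_true(signSatisfies(c(1L, 0L), c(0, 5)))
    expect_false(signSatisfies(c(1L, 0L), c(2, 5)))
    expect_error(signSatisfies(c(1L, 0L, 1L), c(1, 2)))
})

test_that("LP admissibility oracle solves the boxed feasibility program", {
    expect_true(lpFeasible(c(0L, 0L, 0L), c(3, 1, 2)))
    expect_true(lpFeasible(c(1L, -1L), c(2, 1)))        # v = (1, 2) scaled
    expect_false(lpFeasible(c(1L, 0L), c(1, 5)))        # v.w forced > 0
    expect_error(lpFeasible(c(1L), c(1), eps = -1), "solver")
    expect_error(lpFeasible(c(1L), c(1, 2)))
})

test_that("sign-satisfaction and the LP oracle agree on random instances", {
    # magnitudes bounded away from zero keep the eps strict-inequality
    # encoding of the LP exact on this domain
    set.seed(4242)
    for (k in 1:2000) {
        N <- sample(2:6, 1)
        s <- sample(c(-1L, 0L, 1L), N, replace = TRUE)
        w <- sample(c(-1, 0, 1), N, replace = TRUE) * runif(N, 0.1, 1)
        expect_identical(signSatisfies(s, w), lpFeasible(s, w))
    }
})

test_that("brute-force enumeration returns the minimum candidate set", {
    x <- twoTaxonSamples()
    cand <- admissiblePatterns(x, 1)
    got <- apply(cand$patterns, 1, paste, collapse = ",")
    expect_setequal(got, c("0,0", "1,-1", "-1,1"))
    expect_true(cand$informative)
})

test_that("a single sample leaves all sign-patterns admissible", {
    x <- SteadyStateSamples(rbind(c(1, 2, 3)))
    cand <- admissiblePatterns(x, 1)
    expect_equal(nrow(cand$patterns), 3^3)
    expect_false(cand$informative)
})

test_that("candidate sets are negation-closed and contain the zero pattern", {
    set.seed(99)
    for (k in 1:5) {
        mod <- randomNetwork(5, connectivity = 0.5)
        x <- generateSampleSet(mod, omega = 12, presence = "uniform",
                               strict = FALSE)
        cand <- admissiblePatterns(x, sample.int(5, 1))
        keys <- apply(cand$patterns, 1, paste, collapse = ",")
        negKeys <- apply(-cand$patterns, 1, paste, collapse = ",")
        expect_setequal(keys, negKeys)
        expect_true(paste(rep(0L, 5), collapse = ",") %in% keys)
    }
})

test_that("true sign-patterns are admissible for all four dynamics models", {
    set.seed(123)
    for (kind in c("glv", "holling2", "db", "cm")) {
        mod <- randomNetwork(5, connectivity = 0.4, kind = kind)
        x <- generateSampleSet(mod, omega = 10, presence = "uniform",
                               strict = FALSE)
        truth <- jacobianSignTruth(mod)
        for (i in 1:5) {
            if (nrow(samplesWithTaxon(x, i)) == 0) next
            cand <- admissiblePatterns(x, i)
            keys <- apply(cand$patterns, 1, paste, collapse = ",")
            expect_true(paste(truth[i, ], collapse = ",") %in% keys,
                        label = paste("true pattern admissible for", kind))
        }
    }
})

test_that("enumeration refuses communities beyond the complexity guard", {
    expect_error(enumerateSignPatterns(13), "guard")
    expect_silent(enumerateSignPatterns(13, maxN = 13L))
})

test_that("priors orient candidate sets and flag uninformative data", {
    cand <- list(patterns = rbind(c(-1L, 1L), c(0L, 0L), c(1L, -1L)),
                 taxon = 1L)
    expect_identical(resolveSigns(cand), c(-1L, 1L))
    cand3 <- list(patterns = rbind(c(-1L, 0L, 1L), c(0L, 0L, 0L),
                                   c(1L, 0L, -1L)), taxon = 1L)
    expect_identical(resolveSigns(cand3), c(-1L, 0L, 1L))
    # full pattern space: nothing can be concluded
    full <- list(patterns = enumerateSignPatterns(3), taxon = 1L)
    expect_warning(res <- resolveSigns(full), "uninformative")
    expect_true(all(is.na(res)))
    # prior inconsistent with every candidate
    expect_warning(res2 <- resolveSigns(cand, prior = c(0L, 1L)), "consistent")
    expect_true(all(is.na(res2)))
    expect_error(resolveSigns(list(patterns = NULL, taxon = 1L)), "empty")
})

test_that("combinatorial sizes follow from the community size", {
    expect_equal(maxSupportCount(8), 255)
    expect_equal(patternSpaceSize(8), 6561)
})
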