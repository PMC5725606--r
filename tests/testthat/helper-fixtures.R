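## Small fixtures shared across test files; everything is built in code.

## Two-taxon community whose samples are x^{1} = (1, 0) and x^{1,2} = (2, 1):
## adding taxon 2 raises taxon 1, so the true row pattern is s_1 = (-, +).
twoTaxonSamples <- function() {
    SteadyStateSamples(rbind(c(1, 0), c(2, 1)))
}

## Toy GLV used in worked examples: steady state on {1,2} is (1.2, 0.4).
toyGLV <- function() {
    communityModel(A = rbind(c(-1, 0.5), c(-0.5, -1)), r = c(1, 1))
}

## Three-taxon GLV with row pattern s_1 = (-, 0, +): taxon 2 does not affect
## taxon 1, taxon 3 promotes it.  All couplings weak so every support is
## feasible and stable.
threeTaxonGLV <- function() {
    A <- rbind(c(-1, 0, 0.4),
               c(0.2, -1, -0.3),
               c(-0.2, 0.1, -1))
    communityModel(A = A, r = c(1, 0.8, 0.9))
}

## All feasible supports of a model as a SteadyStateSamples object.
allSupportSamples <- function(model) {
    N <- length(model@r)
    rows <- list()
    for (k in seq_len(2^N - 1)) {
        supp <- which(intToBits(k)[1:N] == 1)
        x <- steadyState(model, supp)
        if (!is.null(x)) rows[[length(rows) + 1L]] <- x
    }
    SteadyStateSamples(do.call(rbind, rows))
}
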