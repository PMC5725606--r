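#' Construct a SteadyStateSamples object
#'
#' @param abundance numeric matrix or data.frame of absolute abundances with
#'   samples in rows and taxa in columns (the orientation of a typical sample
#'   table); row names are sample identifiers, column names taxon names.
#'   Missing names are filled in as \code{sample_1, ...} / \code{taxon_1, ...}.
#' @param zeroTol numeric(1), abundance at or below which a taxon counts as
#'   absent (default \code{1e-8}).
#'
#' @return A \linkS4class{SteadyStateSamples} object.
#' @examples
#' x <- SteadyStateSamples(rbind(c(1, 0), c(2, 1)))
#' sampleSupports(x)
#' @export
SteadyStateSamples <- function(abundance, zeroTol = 1e-8) {
    a <- as.matrix(abundance)
    storage.mode(a) <- "double"
    if (is.null(rownames(a)))
        rownames(a) <- paste0("sample_", seq_len(nrow(a)))
    if (is.null(colnames(a)))
        colnames(a) <- paste0("taxon_", seq_len(ncol(a)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = t(a)))
    new("SteadyStateSamples", se, zeroTol = zeroTol)
}

#' Abundance matrix in samples-by-taxa orientation
#'
#' @param x a \linkS4class{SteadyStateSamples} object.
#' @param ... unused.
#' @return numeric matrix, \eqn{\Omega \times N}.
#' @rdname abundances
#' @export
setMethod("abundances", "SteadyStateSamples", function(x, ...) {
    t(SummarizedExperiment::assay(x, "abundance"))
})

#' Per-sample supports (taxa collections)
#'
#' The support \eqn{I} of a sample is the set of taxon indices with abundance
#' strictly above the zero threshold.
#'
#' @param x a \linkS4class{SteadyStateSamples} object.
#' @param ... unused.
#' @return list of integer vectors, one per sample.
#' @rdname sampleSupports
#' @export
setMethod("sampleSupports", "SteadyStateSamples", function(x, ...) {
    a <- abundances(x)
    tol <- x@zeroTol
    lapply(seq_len(nrow(a)), function(i) which(a[i, ] > tol))
})

#' @rdname zeroTol
#' @param x a \linkS4class{SteadyStateSamples} object.
#' @return numeric(1), the zero threshold.
#' @export
setMethod("zeroTol", "SteadyStateSamples", function(x) x@zeroTol)

#' Number of taxa / samples
#'
#' @param x a \linkS4class{SteadyStateSamples} object.
#' @return integer(1).
#' @export
nTaxa <- function(x) nrow(SummarizedExperiment::assay(x, "abundance"))

#' @rdname nTaxa
#' @export
nSamples <- function(x) ncol(SummarizedExperiment::assay(x, "abundance"))

#' Average replicate samples sharing an identical support
#'
#' Samples whose supports coincide are replaced by their per-taxon arithmetic
#' mean, yielding one representative steady state per taxa collection.
#' Averaging across genuinely different steady states on the same support
#' would mask true multi-stability, so run
#' \code{\link{detectMultistability}} first (done automatically by
#' \code{\link{inferSignMatrix}}).
#'
#' @param x a \linkS4class{SteadyStateSamples} object.
#' @param ... unused.
#' @return a \linkS4class{SteadyStateSamples} with one sample per support.
#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "SteadyStateSamples", function(x, ...) {
    a <- abundances(x)
    key <- vapply(sampleSupports(x), paste, character(1), collapse = ",")
    groups <- split(seq_len(nrow(a)), key)
    out <- do.call(rbind, lapply(groups, function(idx) {
        if (length(idx) == 1L) a[idx, , drop = TRUE]
        else colMeans(a[idx, , drop = FALSE])
    }))
    rownames(out) <- vapply(groups, function(idx) rownames(a)[idx[1L]],
                            character(1))
    # keep original sample order (by first occurrence)
    out <- out[order(vapply(groups, min, integer(1))), , drop = FALSE]
    SteadyStateSamples(out, zeroTol = x@zeroTol)
})

#' Samples sharing a given taxon
#'
#' Returns the sub-table \eqn{X_i} of all samples whose support contains
#' taxon \code{taxon} (the samples entering the inference of row \eqn{i} of
#' the Jacobian sign-pattern or of the GLV interaction matrix).
#'
#' @param x a \linkS4class{SteadyStateSamples} object.
#' @param taxon integer(1) taxon index.
#' @return numeric matrix (subset of \code{abundances(x)} rows).
#' @export
samplesWithTaxon <- function(x, taxon) {
    stopifnot(taxon >= 1L, taxon <= nTaxa(x))
    a <- abundances(x)
    a[a[, taxon] > zeroTol(x), , drop = FALSE]
}

setMethod("show", "SteadyStateSamples", function(object) {
    cat("SteadyStateSamples:", nSamples(object), "samples x",
        nTaxa(object), "taxa\n")
    supp <- sampleSupports(object)
    cat("  distinct supports:",
        length(unique(vapply(supp, paste, character(1), collapse = ","))),
        "| zeroTol:", format(object@zeroTol), "\n")
})

setMethod("show", "SignInference", function(object) {
    s <- object@signs
    cat("SignInference (", object@method, "): ", nrow(s), " x ", ncol(s),
        " interaction types\n", sep = "")
    cat("  determined:", sum(!is.na(s)), "/", length(s),
        " (+:", sum(s == 1L, na.rm = TRUE),
        " -:", sum(s == -1L, na.rm = TRUE),
        " 0:", sum(s == 0L, na.rm = TRUE), ")\n")
    if (any(!is.na(object@phi)))
        cat("  mean best phi:",
            round(mean(object@phi, na.rm = TRUE), 3), "\n")
})

setMethod("show", "GLVFit", function(object) {
    cat("GLVFit (", object@method, "): N =", length(object@r), "taxa\n")
    off <- object@A[row(object@A) != col(object@A)]
    cat("  nonzero off-diagonal interactions:", sum(abs(off) > 1e-10), "\n")
    if (nrow(object@diagnostics))
        cat("  median row R^2:",
            round(stats::median(object@diagnostics$r_squared, na.rm = TRUE), 4),
            "\n")
})

setMethod("show", "CommunityModel", function(object) {
    cat("CommunityModel <", object@kind, ">: N =", length(object@r),
        "taxa,", sum(object@A[row(object@A) != col(object@A)] != 0),
        "inter-taxa interactions\n")
})

#' @rdname signMatrix
#' @param x a \linkS4class{SignInference} object.
#' @return integer matrix over \{-1,0,1,NA\}.
#' @export
setMethod("signMatrix", "SignInference", function(x) x@signs)

#' @rdname confidence
#' @param x a \linkS4class{SignInference} object.
#' @return numeric vector of per-taxon best phi scores.
#' @export
setMethod("confidence", "SignInference", function(x) x@phi)

#' @rdname interactionMatrix
#' @param x a \linkS4class{GLVFit} object.
#' @return numeric matrix A.
#' @export
setMethod("interactionMatrix", "GLVFit", function(x) x@A)

#' @rdname growthRates
#' @param x a \linkS4class{GLVFit} object.
#' @return numeric vector r.
#' @export
setMethod("growthRates", "GLVFit", function(x) x@r)

#' @rdname rowDiagnostics
#' @param x a \linkS4class{GLVFit} object.
#' @return data.frame of per-taxon fit diagnostics.
#' @export
setMethod("rowDiagnostics", "GLVFit", function(x) x@diagnostics)
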