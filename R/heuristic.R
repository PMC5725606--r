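## Scalable heuristic for sign-pattern inference: sample (N-1)-subsets of
## pairwise-difference hyperplanes, intersect them into a candidate line,
## and score the line's orthant by the fraction phi of all hyperplanes that
## cross it.

#' Matrix of pairwise sample differences for one taxon
#'
#' Builds \eqn{M_i}: one column \eqn{x^I - x^K} per unordered pair of
#' samples sharing taxon \code{taxon}.  Each column is the normal vector of
#' a hyperplane through the origin that the true row sign-pattern must be
#' able to cross.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param taxon integer(1) taxon index.
#' @return list with \code{M} (N x C(|X_i|,2) numeric matrix), \code{pairs}
#'   (2 x ncol index matrix into the rows of \eqn{X_i}) and \code{taxon}.
#' @export
buildDifferenceMatrix <- function(samples, taxon) {
    Xi <- samplesWithTaxon(samples, taxon)
    if (nrow(Xi) < 2L)
        stop("fewer than 2 samples share taxon ", taxon,
             "; cannot build a difference matrix")
    M <- pairDifferences(Xi, tol = zeroTol(samples))
    list(M = M, pairs = attr(M, "pairs"), taxon = taxon)
}

## Null-space direction of the stack of the chosen columns (as rows).
## Returns the unit direction if the null space is exactly 1-dimensional
## (or, for fewer than N-1 rows, an arbitrary unit kernel basis vector),
## otherwise NULL.
kernelDirection <- function(cols, requireLine = TRUE, svTol = 1e-10) {
    A <- t(cols)                       # rows = hyperplane normals
    N <- ncol(A)
    sv <- svd(A, nu = 0, nv = N)
    d <- sv$d
    rank <- sum(d > svTol * max(d, .Machine$double.eps))
    nullDim <- N - rank
    if (nullDim < 1L) return(NULL)
    if (requireLine && nrow(A) >= N - 1L && nullDim != 1L) return(NULL)
    v <- sv$v[, N]                     # basis vector of the smallest sv
    v / sqrt(sum(v^2))
}

#' Sample one candidate intersection line
#'
#' Draws \eqn{N-1} columns of the difference matrix uniformly without
#' replacement, stacks them, and computes the 1-dimensional kernel of the
#' stack - the line in which the \eqn{N-1} hyperplanes intersect.  If the
#' drawn hyperplanes are degenerate (kernel dimension not 1), the draw is
#' repeated up to \code{retries} times.  When the matrix has fewer than
#' \eqn{N-1} columns, all columns are used and any kernel basis vector is
#' returned.
#'
#' @param diffMat list from \code{\link{buildDifferenceMatrix}}.
#' @param retries integer(1), retry budget for degenerate draws.
#' @param tol numeric(1), sign-extraction threshold applied to the unit
#'   direction vector.
#' @return list with \code{direction} (unit N-vector), \code{pattern}
#'   (integer sign-pattern) and \code{columns} (drawn column indices), or
#'   \code{NULL} when the retry budget is exhausted.
#' @export
sampleIntersectionLine <- function(diffMat, retries = 50L, tol = 0.03) {
    M <- diffMat$M
    N <- nrow(M)
    P <- ncol(M)
    k <- min(N - 1L, P)
    for (t in seq_len(max(1L, retries))) {
        idx <- sample.int(P, k)
        v <- kernelDirection(M[, idx, drop = FALSE],
                             requireLine = P >= N - 1L)
        if (!is.null(v))
            return(list(direction = v, pattern = signOf(v, tol = tol),
                        columns = idx))
    }
    NULL
}

#' Confidence score phi of a candidate line
#'
#' The fraction of all pairwise-difference hyperplanes that cross the three
#' orthants (\eqn{+a}, 0, \eqn{-a}) selected by the line's sign-pattern.
#' \eqn{\phi = 1} means the pattern satisfies the sign-satisfaction
#' constraint for every sample pair.
#'
#' @param pattern integer sign-pattern of the line.
#' @param diffMat list from \code{\link{buildDifferenceMatrix}}.
#' @return numeric(1) in [0, 1].
#' @export
scoreLine <- function(pattern, diffMat) {
    M <- diffMat$M
    if (ncol(M) == 0L) return(1)
    P <- M * as.numeric(pattern)       # column-wise products s_j * w_j
    pos <- colSums(P > 0) > 0
    neg <- colSums(P < 0) > 0
    mean((pos & neg) | (!pos & !neg))
}

## canonical orientation: first non-zero entry positive (candidate sets are
## negation-closed, so patterns are compared up to global sign)
canonicalPattern <- function(p) {
    nz <- which(p != 0L)
    if (length(nz) && p[nz[1L]] < 0L) -p else p
}

#' Heuristic inference of one row's candidate sign-patterns
#'
#' Draws \code{psi} scored intersection lines and returns the candidate set
#' \eqn{\hat S_i = \{-a, 0, a\}} of the most probable maximum-\eqn{\phi}
#' line together with its confidence.  When several lines tie at the
#' maximal \eqn{\phi} with genuinely different sign-patterns (beyond global
#' negation), the pattern sampled most often among the tied draws wins
#' (lines cluster around the direction best supported by the data, so the
#' sampling frequency estimates how probable each candidate is); a
#' persistent tie falls to the first-sampled pattern, keeping results
#' seed-reproducible.  All tied patterns are kept in the report.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param taxon integer(1) taxon index.
#' @param psi integer(1) >= 1, number of intersection lines to draw
#'   (the solution-space size of the heuristic).
#' @param retries per-line retry budget for degenerate draws.
#' @param tol sign-extraction threshold for line directions.
#' @return list with \code{patterns} (integer matrix of maximal canonical
#'   patterns plus their negations and the zero pattern), \code{maxPatterns}
#'   (canonical maximal patterns only), \code{phi} (best score),
#'   \code{lines} (data.frame log of all scored lines), \code{taxon}; or
#'   phi = NA and empty patterns when no valid line was found.
#' @export
heuristicInferRow <- function(samples, taxon, psi = 5L * nTaxa(samples),
                              retries = 50L, tol = 0.03) {
    stopifnot(psi >= 1L)
    dm <- buildDifferenceMatrix(samples, taxon)
    N <- nrow(dm$M)
    dirs <- vector("list", psi)
    phis <- rep(NA_real_, psi)
    pats <- vector("list", psi)
    for (l in seq_len(psi)) {
        line <- sampleIntersectionLine(dm, retries = retries, tol = tol)
        if (is.null(line)) next
        dirs[[l]] <- line$direction
        pats[[l]] <- line$pattern
        phis[l] <- scoreLine(line$pattern, dm)
    }
    ok <- which(!is.na(phis))
    if (length(ok) == 0L)
        return(list(patterns = matrix(integer(0), 0L, N),
                    maxPatterns = matrix(integer(0), 0L, N),
                    phi = NA_real_, lines = NULL, taxon = taxon))
    best <- max(phis[ok])
    maximal <- ok[phis[ok] == best]
    ## "most probable" line: among the max-phi draws, vote by how often each
    ## (negation-canonical) sign-pattern was sampled; persistent ties fall to
    ## the first-sampled pattern, keeping runs seed-reproducible
    keys <- vapply(pats[maximal], function(p)
        paste(canonicalPattern(p), collapse = " "), character(1))
    tab <- table(keys)
    winners <- names(tab)[tab == max(tab)]
    winKey <- keys[keys %in% winners][1L]
    maxP <- matrix(as.integer(strsplit(winKey, " ")[[1L]]), nrow = 1L)
    tied <- unique(lapply(pats[maximal], canonicalPattern))
    full <- rbind(maxP, -maxP, rep(0L, N))
    lines <- data.frame(line = ok, phi = phis[ok])
    lines$pattern <- vapply(pats[ok], paste, character(1), collapse = "")
    list(patterns = full, maxPatterns = maxP, phi = best,
         tiedPatterns = tied, lines = lines, taxon = taxon)
}

#' Infer the full interaction-type (sign) matrix
#'
#' Row-by-row inference of the sign-pattern of the community Jacobian from
#' steady-state samples, by either the brute-force enumeration
#' (\code{\link{admissiblePatterns}}; practical for roughly a dozen taxa or
#' fewer) or the heuristic intersection-line algorithm
#' (\code{\link{heuristicInferRow}}).  Each row's negation-closed candidate
#' set is oriented with \code{\link{resolveSigns}} using the prior
#' (default: negative intra-taxa interaction, \eqn{s_{ii} = -}).
#'
#' Two assumption guards run first: samples whose row sums are all equal
#' (relative/compositional abundances) are rejected outright, because every
#' intersection line then degenerates to the all-ones direction; and samples
#' providing evidence of true multi-stability (two samples sharing a support
#' but differing beyond tolerance) abort sign inference, since they falsify
#' the constant-sign assumption.  Replicates sharing a support are averaged
#' before inference when \code{average = TRUE}.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param method \code{"heuristic"} or \code{"bruteforce"}.
#' @param prior NULL (default: diagonal -1) or an N x N integer matrix over
#'   \{-1,0,1,NA\} of known interaction signs (row i is the prior for
#'   taxon i's sign-pattern).
#' @param psi heuristic solution-space size (default 5N).
#' @param average average replicate samples sharing a support (default TRUE).
#' @param guard run the compositionality and multistability guards
#'   (default TRUE).
#' @param maxN brute-force complexity guard (default 12).
#' @param retries,tol forwarded to the heuristic row inference.
#' @return a \linkS4class{SignInference} object.
#' @examples
#' mod <- randomNetwork(5, connectivity = 0.5)
#' x <- generateSampleSet(mod, omega = 20, presence = "uniform")
#' inferSignMatrix(x, method = "bruteforce")
#' @export
inferSignMatrix <- function(samples, method = c("heuristic", "bruteforce"),
                            prior = NULL, psi = 5L * nTaxa(samples),
                            average = TRUE, guard = TRUE, maxN = 12L,
                            retries = 50L, tol = 0.03) {
    method <- match.arg(method)
    N <- nTaxa(samples)
    if (guard) {
        if (compositionalityCheck(samples))
            stop("samples look compositional (all row sums equal): relative ",
                 "abundances defeat steady-state sign inference; provide ",
                 "absolute abundances")
        ms <- detectMultistability(samples)
        if (ms$multistable)
            stop("true multi-stability detected (same support, different ",
                 "steady states): the constant-sign assumption is falsified; ",
                 "only the zero-pattern (network structure) can be inferred")
    }
    if (average)
        samples <- averageReplicates(samples)
    if (!is.null(prior))
        stopifnot(is.matrix(prior), nrow(prior) == N, ncol(prior) == N)
    signs <- matrix(NA_integer_, N, N,
                    dimnames = list(colnames(abundances(samples)),
                                    colnames(abundances(samples))))
    phi <- rep(NA_real_, N)
    counts <- rep(NA_integer_, N)
    report <- vector("list", N)
    for (i in seq_len(N)) {
        rowPrior <- if (is.null(prior)) NULL else prior[i, ]
        res <- tryCatch({
            if (method == "bruteforce") {
                cand <- admissiblePatterns(samples, i, maxN = maxN)
                counts[i] <- nrow(cand$patterns)
                report[[i]] <- list(candidates = nrow(cand$patterns),
                                    informative = cand$informative)
                resolveSigns(cand, prior = rowPrior)
            } else {
                row <- heuristicInferRow(samples, i, psi = psi,
                                         retries = retries, tol = tol)
                phi[i] <- row$phi
                counts[i] <- nrow(row$maxPatterns)
                report[[i]] <- list(lines = row$lines, phi = row$phi)
                if (is.na(row$phi)) rep(NA_integer_, N)
                else resolveRowFromPatterns(row, i, rowPrior)
            }
        }, error = function(e) {
            warning("taxon ", i, ": ", conditionMessage(e),
                    " (row left undetermined)")
            rep(NA_integer_, N)
        })
        signs[i, ] <- res
    }
    new("SignInference", signs = signs, method = method, phi = phi,
        candidateCounts = counts, report = report,
        parameters = list(psi = if (method == "heuristic") psi else NA,
                          zeroTol = zeroTol(samples), average = average))
}

## Orient each tied maximal pattern with the prior and keep only entries on
## which all orientable patterns agree.
resolveRowFromPatterns <- function(row, taxon, prior = NULL) {
    N <- ncol(row$patterns)
    maxP <- row$maxPatterns
    resolved <- lapply(seq_len(nrow(maxP)), function(k) {
        cand <- list(patterns = rbind(maxP[k, ], -maxP[k, ],
                                      rep(0L, N)), taxon = taxon)
        suppressWarnings(resolveSigns(cand, prior = prior))
    })
    out <- resolved[[1L]]
    if (length(resolved) > 1L)
        for (k in seq_along(resolved)[-1L]) {
            disagree <- is.na(resolved[[k]]) | is.na(out) |
                resolved[[k]] != out
            out[disagree] <- NA_integer_
        }
    out
}
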