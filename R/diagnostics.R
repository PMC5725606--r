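## Assumption guards, evaluation metrics, and study-style analyses:
## multistability detection, compositionality guard, relative yield,
## invasion-response prediction, accuracy/FDR, robustness to noise, and
## minimal-sample-size experiments.

#' Detect true multi-stability in a sample set
#'
#' A community displays true multi-stability when some subset of taxa admits
#' several distinct positive steady states.  Operationally: two samples
#' share an identical support but differ in abundance beyond a relative
#' tolerance.  Its presence falsifies the constant-sign assumption, so sign
#' inference must be refused (only the zero-pattern, i.e. network
#' structure, remains inferable).
#'
#' @param samples a \linkS4class{SteadyStateSamples} object (raw, before
#'   replicate averaging).
#' @param tol relative L-infinity tolerance between same-support samples
#'   (default 0.05).
#' @return list with \code{multistable} flag and \code{groups}, a list of
#'   offending support index vectors.
#' @export
detectMultistability <- function(samples, tol = 0.05) {
    a <- abundances(samples)
    key <- vapply(sampleSupports(samples), paste, character(1),
                  collapse = ",")
    offend <- list()
    for (g in split(seq_len(nrow(a)), key)) {
        if (length(g) < 2L) next
        block <- a[g, , drop = FALSE]
        ref <- block[1L, ]
        scale <- max(abs(ref), 1e-12)
        dev <- max(abs(sweep(block, 2L, ref))) / scale
        if (dev > tol)
            offend[[length(offend) + 1L]] <-
                unname(which(block[1L, ] > zeroTol(samples)))
    }
    list(multistable = length(offend) > 0L, groups = offend)
}

#' Compositionality (relative-abundance) guard
#'
#' Relative abundances sum to a constant, which makes every sample
#' difference orthogonal to the all-ones vector; the intersection-line
#' heuristic then always proposes the all-positive sign-pattern and the
#' inference is meaningless.  This guard flags sample sets whose row sums
#' are all equal within a relative tolerance.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param tol relative tolerance on the spread of row sums (default 1e-6).
#' @return logical(1); TRUE means the data look compositional.  A single
#'   sample passes with a warning (undecidable).
#' @export
compositionalityCheck <- function(samples, tol = 1e-6) {
    s <- rowSums(abundances(samples))
    if (length(s) < 2L) {
        warning("single sample: compositionality undecidable")
        return(FALSE)
    }
    (max(s) - min(s)) <= tol * max(max(abs(s)), 1e-12)
}

#' Relative yield of pairwise co-culture versus monoculture
#'
#' \eqn{R_{ij} = (x_i^{\{i,j\}} - x_i^{\{i\}}) / (x_i^{\{i,j\}} +
#' x_i^{\{i\}})}: the normalized change of taxon \eqn{i}'s abundance when
#' grown with taxon \eqn{j} relative to monoculture.  Negative values
#' indicate growth hindrance by \eqn{j}, positive values facilitation; the
#' sign is a ground-truth proxy for the interaction type of \eqn{j} on
#' \eqn{i}.
#'
#' @param samples a \linkS4class{SteadyStateSamples} holding (at least) the
#'   monoculture sample of taxon \code{i} and the \code{\{i,j\}} co-culture
#'   sample.
#' @param i,j taxon indices (focal taxon \code{i}, competitor \code{j}).
#' @return numeric(1) in [-1, 1].
#' @export
relativeYield <- function(samples, i, j) {
    a <- abundances(samples)
    supp <- vapply(sampleSupports(samples), paste, character(1),
                   collapse = ",")
    mono <- which(supp == as.character(i))
    duo <- which(supp == paste(sort(c(i, j)), collapse = ","))
    if (length(mono) == 0L || length(duo) == 0L)
        stop("missing monoculture {", i, "} or pair culture {", i, ",", j,
             "} sample")
    xm <- mean(a[mono, i]); xd <- mean(a[duo, i])
    if (xm <= 0 || xd <= 0)
        stop("focal taxon must be present in both samples")
    (xd - xm) / (xd + xm)
}

#' Predict abundance responses to adding an invader taxon
#'
#' The direct effect of adding taxon \code{invader} to a community is read
#' off the invader's column of the interaction-sign matrix: resident
#' \eqn{i} is predicted to increase when \eqn{s_{i,invader} = +}, decrease
#' when \eqn{-}, and stay unchanged when 0.  Undetermined entries yield
#' \code{"unpredictable"}.  (Only direct interactions enter; indirect
#' effects through other residents are ignored.)
#'
#' @param signs integer sign matrix (or a \linkS4class{SignInference}).
#' @param invader integer(1) column index of the introduced taxon.
#' @return character vector over \code{c("increase", "decrease",
#'   "no-change", "unpredictable")}, one per resident taxon (the invader's
#'   own entry is \code{NA}).
#' @export
predictInvasionResponse <- function(signs, invader) {
    if (is(signs, "SignInference")) signs <- signMatrix(signs)
    col <- signs[, invader]
    out <- rep("unpredictable", nrow(signs))
    out[!is.na(col) & col == 1L] <- "increase"
    out[!is.na(col) & col == -1L] <- "decrease"
    out[!is.na(col) & col == 0L] <- "no-change"
    out[invader] <- NA_character_
    out
}

#' Accuracy and error decomposition of an inferred sign matrix
#'
#' Compares inferred interaction types with the ground truth and reports
#' the percentage of correctly inferred signs, the percentage falsely
#' inferred, and the undetermined count.  By default the denominator is the
#' full matrix including the diagonal (undetermined entries count against
#' accuracy); \code{denominator = "determined"} restricts to determined
#' entries and \code{offDiagonal = TRUE} drops the diagonal.
#'
#' @param inferred integer sign matrix (or \linkS4class{SignInference}).
#' @param truth integer sign matrix of the same shape.
#' @param denominator \code{"all"} (default) or \code{"determined"}.
#' @param offDiagonal exclude the diagonal (default FALSE).
#' @return list with \code{accuracy} (percent), \code{false_percent},
#'   \code{undetermined} (count), \code{n_determined}, \code{n_entries}.
#' @export
signAccuracy <- function(inferred, truth, denominator = c("all", "determined"),
                         offDiagonal = FALSE) {
    if (is(inferred, "SignInference")) inferred <- signMatrix(inferred)
    denominator <- match.arg(denominator)
    if (!all(dim(inferred) == dim(truth)))
        stop("inferred and truth sign matrices must have the same shape")
    keep <- if (offDiagonal) row(truth) != col(truth) else
        matrix(TRUE, nrow(truth), ncol(truth))
    inf <- inferred[keep]; tru <- truth[keep]
    det <- !is.na(inf)
    nCorrect <- sum(det & inf == tru)
    nFalse <- sum(det & inf != tru)
    denom <- if (denominator == "all") length(inf) else sum(det)
    list(accuracy = if (denom > 0) 100 * nCorrect / denom else NA_real_,
         false_percent = if (denom > 0) 100 * nFalse / denom else NA_real_,
         undetermined = sum(!det),
         n_determined = sum(det),
         n_entries = length(inf))
}

#' False-discovery rate of an inferred interaction matrix
#'
#' Matrix-wide over off-diagonal entries: the fraction of inferred non-zero
#' interactions that are truly zero.
#'
#' @param inferredA inferred interaction matrix (or \linkS4class{GLVFit}).
#' @param trueA true interaction matrix.
#' @return numeric(1) in [0, 1] (0 when nothing was selected).
#' @export
interactionFDR <- function(inferredA, trueA) {
    if (is(inferredA, "GLVFit")) inferredA <- interactionMatrix(inferredA)
    off <- row(trueA) != col(trueA)
    sel <- inferredA[off] != 0
    if (!any(sel)) return(0)
    sum(sel & trueA[off] == 0) / sum(sel)
}

#' Robustness of inferred signs to measurement noise
#'
#' Re-runs sign inference on noise-perturbed copies of the samples and
#' reports, per noise level and matrix entry, the percentage of
#' realizations whose inferred sign equals the noiseless inference.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param etaGrid numeric vector of noise levels.
#' @param reps realizations per level (default 50).
#' @param inferFn function(samples) returning a sign matrix or
#'   \linkS4class{SignInference}; default brute-force
#'   \code{\link{inferSignMatrix}}.
#' @return list with \code{baseline} (noiseless sign matrix) and
#'   \code{unchanged}, a list (one N x N percentage matrix per eta).
#' @export
robustnessAnalysis <- function(samples, etaGrid, reps = 50L,
                               inferFn = NULL) {
    stopifnot(reps >= 2L)
    if (is.null(inferFn))
        inferFn <- function(s) inferSignMatrix(s, method = "bruteforce")
    asMat <- function(x) if (is(x, "SignInference")) signMatrix(x) else x
    base <- asMat(inferFn(samples))
    out <- lapply(etaGrid, function(eta) {
        same <- matrix(0, nrow(base), ncol(base))
        for (k in seq_len(reps)) {
            pert <- if (eta == 0) samples else addNoise(samples, eta)
            s <- asMat(inferFn(pert))
            agree <- !is.na(s) & !is.na(base) & s == base
            same <- same + agree
        }
        100 * same / reps
    })
    names(out) <- as.character(etaGrid)
    list(baseline = base, unchanged = out)
}

## mean full-matrix sign accuracy at a given sample size, over `reps`
## independent network + sample-set realizations
meanAccuracyAtOmega <- function(kind, N, omega, presence, psi,
                                reps = 10L, connectivity = 0.4,
                                method = "heuristic", eta = 0) {
    acc <- numeric(0)
    for (k in seq_len(reps)) {
        mod <- randomNetwork(N, connectivity = connectivity, kind = kind)
        x <- tryCatch(
            generateSampleSet(mod, omega = omega, presence = presence,
                              strict = FALSE),
            error = function(e) NULL)
        if (is.null(x) || nSamples(x) < 2L) next
        if (eta > 0) x <- addNoise(x, eta)
        inf <- suppressWarnings(
            inferSignMatrix(x, method = method, psi = psi, guard = FALSE))
        acc <- c(acc, signAccuracy(inf, jacobianSignTruth(mod))$accuracy)
    }
    if (length(acc) == 0L) NA_real_ else mean(acc)
}

#' Minimal sample size for accurate sign inference
#'
#' For each community size \eqn{N}, finds by bisection the smallest sample
#' size \eqn{\Omega^*} at which the mean full-matrix sign accuracy (over
#' \code{reps} independent network and sample-set realizations) reaches
#' \code{accuracyTarget}.  A linear fit of \eqn{\Omega^*} against \eqn{N}
#' is reported alongside.
#'
#' @param NGrid integer vector of community sizes.
#' @param kind dynamics kind (default \code{"glv"}).
#' @param presence taxon-presence pattern (see \code{\link{drawSupport}}).
#' @param accuracyTarget percent accuracy to reach (default 95).
#' @param psiFactor heuristic lines per taxon, \eqn{\Psi = psiFactor \cdot
#'   N} (default 10).
#' @param reps realizations per evaluated sample size (default 10).
#' @param connectivity network connectivity (default 0.4).
#' @param omegaCap upper bound on the searched sample size as a multiple of
#'   N (default 8); targets unreachable below the cap are reported as
#'   censored (\code{NA}).
#' @return list with \code{omegaStar} (named numeric per N; NA = censored)
#'   and \code{slope} of the linear fit.
#' @export
minSampleSize <- function(NGrid, kind = "glv", presence = "uniform",
                          accuracyTarget = 95, psiFactor = 10L,
                          reps = 10L, connectivity = 0.4, omegaCap = 8) {
    stopifnot(accuracyTarget > 0, accuracyTarget <= 100)
    omegaStar <- setNames(rep(NA_real_, length(NGrid)), NGrid)
    for (idx in seq_along(NGrid)) {
        N <- NGrid[idx]
        lo <- 2L
        hi <- min(as.integer(omegaCap * N), as.integer(maxSupportCount(N)))
        ok <- function(om) {
            a <- meanAccuracyAtOmega(kind, N, om, presence,
                                     psi = psiFactor * N, reps = reps,
                                     connectivity = connectivity)
            !is.na(a) && a >= accuracyTarget
        }
        if (!ok(hi)) next                       # censored at the cap
        while (hi - lo > 1L) {
            mid <- (lo + hi) %/% 2L
            if (ok(mid)) hi <- mid else lo <- mid
        }
        omegaStar[idx] <- hi
    }
    known <- !is.na(omegaStar)
    slope <- if (sum(known) >= 2L)
        unname(coef(lm(omegaStar[known] ~ NGrid[known]))[2L]) else NA_real_
    list(omegaStar = omegaStar, slope = slope)
}

#' Plateau accuracy of heuristic sign inference
#'
#' Grows the sample size in steps of \eqn{N} and evaluates the mean
#' full-matrix sign accuracy (over \code{reps} network realizations) at
#' each step, stopping once the accuracy stops improving by more than
#' \code{improveTol} percentage points or the step cap is reached; returns
#' the accuracy at the plateau.
#'
#' @param kind dynamics kind.
#' @param N community size.
#' @param psiFactor heuristic lines per taxon (default 10).
#' @param reps realizations per sample size (default 10).
#' @param connectivity network connectivity (default 0.4).
#' @param maxSteps cap on the number of \eqn{\Omega}-steps (default 8).
#' @param improveTol plateau detection threshold in percentage points
#'   (default 0.5).
#' @param presence taxon-presence pattern.
#' @return list with \code{accuracy} (plateau mean accuracy, percent),
#'   \code{omega} (sample size at the plateau) and \code{trace}
#'   (data.frame of all evaluated sizes).
#' @export
plateauAccuracy <- function(kind, N, psiFactor = 10L, reps = 10L,
                            connectivity = 0.4, maxSteps = 8L,
                            improveTol = 0.5, presence = "uniform") {
    omegas <- pmin(seq_len(maxSteps) * N + 2L * N,
                   as.integer(maxSupportCount(N)))
    omegas <- unique(omegas)
    accs <- numeric(0)
    for (k in seq_along(omegas)) {
        accs[k] <- meanAccuracyAtOmega(kind, N, omegas[k], presence,
                                       psi = psiFactor * N, reps = reps,
                                       connectivity = connectivity)
        if (k >= 2L && !is.na(accs[k]) && !is.na(accs[k - 1L]) &&
            accs[k] - accs[k - 1L] <= improveTol)
            break
    }
    used <- seq_along(accs)
    best <- which.max(accs)
    list(accuracy = accs[best], omega = omegas[best],
         trace = data.frame(omega = omegas[used], accuracy = accs))
}
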