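## Ternary sign machinery: orthant-crossing feasibility of hyperplanes, the
## LP admissibility oracle, and brute-force enumeration of admissible
## row sign-patterns.

#' Numerical sign extraction
#'
#' @param v numeric vector.
#' @param tol non-negative numeric(1); entries with \code{abs(v) <= tol} map
#'   to 0.
#' @return integer vector over \{-1, 0, +1\}.
#' @examples
#' signOf(c(1e-12, -1), tol = 1e-9)  # c(0L, -1L)
#' @export
signOf <- function(v, tol = 0) {
    stopifnot(tol >= 0)
    s <- integer(length(v))
    s[v > tol] <- 1L
    s[v < -tol] <- -1L
    s
}

#' Sign-satisfaction test: can a vector with sign-pattern s be orthogonal to w?
#'
#' Decides whether there exists a real vector \eqn{y} with
#' \eqn{sign(y) = s} and \eqn{y \cdot w = 0}; geometrically, whether the
#' hyperplane orthogonal to \eqn{w} crosses the (closed) orthant selected by
#' \eqn{s}.  The combinatorial characterization used here: feasible iff
#' either (a) \eqn{s_j w_j = 0} for every \eqn{j} (the constrained entries of
#' \eqn{w} vanish), or (b) the products \eqn{s_j w_j} take both strict signs,
#' so positive and negative contributions can be balanced.
#'
#' @param s integer vector over \{-1,0,+1\} (a candidate sign-pattern).
#' @param w numeric vector of the same length (a sample-pair difference).
#' @param tol non-negative numeric(1); entries of \code{w} with magnitude at
#'   or below \code{tol} are treated as exact zeros.
#' @return logical(1).
#' @examples
#' signSatisfies(c(1L, 1L), c(1, -1))   # TRUE: y = (1, 1)
#' signSatisfies(c(1L, 1L), c(1, 1))    # FALSE
#' @export
signSatisfies <- function(s, w, tol = 0) {
    if (length(s) != length(w))
        stop("sign-pattern and vector must have the same length")
    wz <- w
    wz[abs(wz) <= tol] <- 0
    p <- as.numeric(s) * wz
    all(p == 0) || (any(p > 0) && any(p < 0))
}

#' Linear-programming admissibility oracle
#'
#' Decides feasibility of the linear program "find \eqn{v \in R^N} with
#' \eqn{v \cdot w = 0} and \eqn{sign(v) = s}", with the open sign constraints
#' encoded as \eqn{v_j \ge eps} (or \eqn{\le -eps}) on the unit box
#' \eqn{|v_j| \le 1}, and \eqn{v_j = 0} for \eqn{s_j = 0}.  Because the
#' objective region is a box, the attainable range of \eqn{v \cdot w} is the
#' closed interval between the box-constrained minimum and maximum of a
#' linear function, both available in closed form; the program is feasible
#' iff that interval contains 0.  This is an independent route from
#' \code{\link{signSatisfies}} and must agree with it whenever the entries of
#' \code{w} are not separated by more than a factor \code{1/eps} in
#' magnitude.
#'
#' @param s integer vector over \{-1,0,+1\}.
#' @param w numeric vector, same length as \code{s}.
#' @param eps positive numeric(1), strict-inequality margin (default 1e-6).
#' @return logical(1).
#' @examples
#' lpFeasible(c(1L, -1L), c(2, 1))  # TRUE: v = (1, 2)/2
#' lpFeasible(c(1L, 0L), c(1, 5))   # FALSE
#' @export
lpFeasible <- function(s, w, eps = 1e-6) {
    if (length(s) != length(w))
        stop("sign-pattern and vector must have the same length")
    if (!is.finite(eps) || eps <= 0 || eps > 1)
        stop("lpFeasible: invalid strict-inequality margin eps (solver setup failure)")
    ## per-coordinate attainable interval of v_j * w_j
    lo <- hi <- numeric(length(s))
    pos <- s > 0L; neg <- s < 0L
    lo[pos] <- pmin(eps * w[pos], w[pos]); hi[pos] <- pmax(eps * w[pos], w[pos])
    lo[neg] <- pmin(-eps * w[neg], -w[neg]); hi[neg] <- pmax(-eps * w[neg], -w[neg])
    sum(lo) <= 0 && sum(hi) >= 0
}

#' Count of possible steady-state supports
#'
#' For N taxa, each non-empty subset of taxa can host at most one stable
#' steady state under a constant-sign Jacobian, so the number of possible
#' steady-state samples is \eqn{2^N - 1}.
#'
#' @param N integer(1) number of taxa.
#' @return numeric(1), \eqn{2^N - 1}.
#' @export
maxSupportCount <- function(N) 2^N - 1

#' Size of the ternary sign-pattern solution space
#'
#' @param N integer(1) number of taxa.
#' @return numeric(1), \eqn{3^N}.
#' @export
patternSpaceSize <- function(N) 3^N

#' Enumerate all ternary sign-patterns of length N
#'
#' @param N integer(1); refuses N > maxN since the space grows as \eqn{3^N}.
#' @param maxN integer(1), guard (default 12); enumeration beyond roughly a
#'   dozen taxa is impractical and the heuristic path should be used instead.
#' @return integer matrix with \eqn{3^N} rows.
#' @export
enumerateSignPatterns <- function(N, maxN = 12L) {
    if (N > maxN)
        stop("enumerateSignPatterns: N = ", N, " exceeds the complexity guard (",
             maxN, "); use the heuristic algorithm or raise maxN explicitly")
    as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), N), KEEP.OUT.ATTRS = FALSE))
}

## Pairwise sample differences x^I - x^K for all unordered pairs of rows of
## `rows` (a |X_i| x N matrix); columns of the result are the difference
## vectors. Entries with magnitude <= tol are zeroed.
pairDifferences <- function(rows, tol = 0) {
    n <- nrow(rows)
    if (n < 2L)
        return(matrix(numeric(0), nrow = ncol(rows), ncol = 0))
    pairs <- utils::combn(n, 2L)
    d <- t(rows[pairs[1L, ], , drop = FALSE] - rows[pairs[2L, ], , drop = FALSE])
    d[abs(d) <= tol] <- 0
    attr(d, "pairs") <- pairs
    d
}

#' Brute-force enumeration of admissible sign-patterns for one taxon
#'
#' Enumerates all \eqn{3^N} ternary sign-patterns and keeps those that
#' satisfy the orthogonality (sign-satisfaction) constraint against every
#' pairwise difference \eqn{x^I - x^K} of samples sharing the taxon.  The
#' result is the minimum candidate set \eqn{\hat S_i} containing the true
#' row sign-pattern \eqn{s_i}; it always contains the all-zero pattern and
#' is closed under negation.  With informative data it shrinks to exactly
#' three patterns \eqn{\{-a, 0, a\}}.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object (replicate
#'   samples sharing a support should be averaged upstream; see
#'   \code{\link{averageReplicates}}).
#' @param taxon integer(1) taxon index i.
#' @param maxN complexity guard forwarded to
#'   \code{\link{enumerateSignPatterns}}.
#' @return list with elements \code{patterns} (integer matrix of admissible
#'   patterns, one per row), \code{taxon}, and \code{informative}
#'   (TRUE iff exactly 3 patterns remain).
#' @export
admissiblePatterns <- function(samples, taxon, maxN = 12L) {
    Xi <- samplesWithTaxon(samples, taxon)
    if (nrow(Xi) == 0L)
        stop("taxon ", taxon, " is absent from all samples")
    N <- ncol(Xi)
    S <- enumerateSignPatterns(N, maxN = maxN)
    D <- pairDifferences(Xi, tol = zeroTol(samples))
    keep <- rep(TRUE, nrow(S))
    for (k in seq_len(ncol(D))) {         # early exit per hyperplane
        if (!any(keep)) break
        P <- S[keep, , drop = FALSE] %*% diag(D[, k], nrow = N)
        pos <- rowSums(P > 0) > 0
        negp <- rowSums(P < 0) > 0
        keep[keep] <- (pos & negp) | (!pos & !negp)
    }
    list(patterns = S[keep, , drop = FALSE], taxon = taxon,
         informative = sum(keep) == 3L)
}

#' Resolve a candidate sign-pattern set using prior sign knowledge
#'
#' Candidate sets produced by the brute-force or heuristic algorithms are
#' closed under negation, so at least one known interaction sign is needed
#' to orient them.  The default prior is the stability assumption that the
#' intra-taxa interaction is negative (\eqn{s_{ii} = -}).  Candidates
#' inconsistent with the prior are dropped; each entry of the returned
#' pattern is fixed where all surviving non-zero candidates agree, and
#' marked undetermined (\code{NA}) otherwise.
#'
#' @param candidates list as returned by \code{\link{admissiblePatterns}}
#'   (fields \code{patterns}, \code{taxon}).
#' @param prior integer vector of length N over \{-1,0,1,NA\}; \code{NA}
#'   means unconstrained.  Default: \code{-1} at the taxon's own position,
#'   \code{NA} elsewhere.
#' @return integer vector over \{-1,0,1,NA\}; all-\code{NA} (with a warning)
#'   when no candidate is consistent with the prior.
#' @export
resolveSigns <- function(candidates, prior = NULL) {
    P <- candidates$patterns
    if (is.null(P) || nrow(P) == 0L)
        stop("resolveSigns: empty candidate set")
    N <- ncol(P)
    if (is.null(prior)) {
        prior <- rep(NA_integer_, N)
        prior[candidates$taxon] <- -1L
    }
    stopifnot(length(prior) == N)
    spec <- which(!is.na(prior))
    if (length(spec) == 0L)
        stop("resolveSigns: prior must specify at least one sign")
    if (nrow(P) >= 3^N) {
        ## the full pattern space: the data carried no information, so not
        ## even the prior-constrained entries count as inferred
        warning("candidate set is the full sign-pattern space; ",
                "data uninformative, all signs undetermined")
        return(rep(NA_integer_, N))
    }
    nonzero <- rowSums(P != 0L) > 0L
    consistent <- nonzero
    for (j in spec)
        consistent <- consistent & (P[, j] == prior[j])
    if (!any(consistent)) {
        warning("no candidate sign-pattern is consistent with the prior; ",
                "all signs undetermined")
        return(rep(NA_integer_, N))
    }
    surv <- P[consistent, , drop = FALSE]
    out <- rep(NA_integer_, N)
    for (j in seq_len(N)) {
        u <- unique(surv[, j])
        if (length(u) == 1L) out[j] <- u
    }
    out
}
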