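## Quantitative GLV inference: hyperplane consistency check, exact per-row
## recovery, Lasso sparsification, and orchestration with knockoff FDR
## control.

## Per-row regression design: over the samples containing `taxon`,
## response y = x_i and predictors the abundances of all other taxa.
## Under GLV, -a_ii x_i = sum_{j != i} a_ij x_j + r_i holds exactly at
## steady state, so the coefficients on the predictors are the a_ij and the
## intercept is r_i once y is scaled by -a_ii.
rowDesign <- function(samples, taxon) {
    Xi <- samplesWithTaxon(samples, taxon)
    if (nrow(Xi) == 0L)
        stop("taxon ", taxon, " is absent from all samples")
    list(X = Xi[, -taxon, drop = FALSE], y = Xi[, taxon],
         predictors = setdiff(seq_len(ncol(Xi)), taxon), n = nrow(Xi))
}

#' GLV consistency check for one taxon
#'
#' Under generalized Lotka-Volterra dynamics all steady-state samples
#' containing taxon \eqn{i} lie exactly on a hyperplane; the coefficient of
#' determination \eqn{R^2} of the multiple linear regression of \eqn{x_i}
#' on the other taxa therefore measures how consistent the data are with
#' GLV dynamics for that row.  \eqn{R^2} near 1 supports quantitative
#' strength inference; low values mean only interaction types should be
#' inferred.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param taxon integer(1) taxon index.
#' @return list with \code{r_squared}, \code{n_samples} and
#'   \code{underdetermined} (TRUE when there are fewer samples than taxa,
#'   so a hyperplane fits trivially).
#' @export
glvConsistency <- function(samples, taxon) {
    d <- rowDesign(samples, taxon)
    N <- nTaxa(samples)
    under <- d$n < N
    if (d$n < 2L)
        return(list(r_squared = NA_real_, n_samples = d$n,
                    underdetermined = TRUE))
    if (sd(d$y) == 0)   # constant abundance: the flat hyperplane is exact
        return(list(r_squared = 1, n_samples = d$n, underdetermined = under))
    fit <- lm(d$y ~ d$X)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    list(r_squared = r2, n_samples = d$n, underdetermined = under)
}

#' Exact (least-squares) recovery of one GLV row with a pinned diagonal
#'
#' Solves the homogeneous system \eqn{a_i \cdot (x^I - x^K) = 0} over all
#' sample pairs sharing the taxon, with \eqn{a_{ii}} pinned to a known
#' value.  On noiseless GLV data with enough samples the solution is exact;
#' a rank-deficient system yields the minimum-norm least-squares solution
#' and is flagged (its off-diagonal entries are then relative strengths in
#' units of \eqn{a_{ii}}).
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param taxon integer(1) taxon index.
#' @param aii numeric(1) != 0, known intra-taxa interaction strength.
#' @return list with \code{a} (full-length row), \code{rankDeficient}
#'   flag, and \code{n_pairs}.
#' @export
fitRowExact <- function(samples, taxon, aii = -1) {
    stopifnot(aii != 0)
    Xi <- samplesWithTaxon(samples, taxon)
    if (nrow(Xi) < 2L)
        stop("need at least 2 samples sharing taxon ", taxon)
    D <- t(pairDifferences(Xi, tol = 0))   # pairs x N
    N <- ncol(D)
    rhs <- -aii * D[, taxon]
    B <- D[, -taxon, drop = FALSE]
    sv <- svd(B)
    tolr <- max(dim(B)) * .Machine$double.eps * max(sv$d, 0)
    pos <- sv$d > tolr
    rankDef <- sum(pos) < ncol(B)
    coefs <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
    a <- numeric(N)
    a[taxon] <- aii
    a[-taxon] <- as.numeric(coefs)
    list(a = a, rankDeficient = rankDef, n_pairs = nrow(D))
}

#' Growth-rate estimate from a fitted row
#'
#' \eqn{r_i} is the average of \eqn{-a_i \cdot x^I} over all steady-state
#' samples containing taxon \eqn{i} (each such sample satisfies
#' \eqn{a_i \cdot x^I + r_i = 0} exactly under noiseless GLV dynamics).
#'
#' @param a numeric row vector of interaction strengths.
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param taxon integer(1) taxon index.
#' @return numeric(1).
#' @export
estimateGrowthRate <- function(a, samples, taxon) {
    Xi <- samplesWithTaxon(samples, taxon)
    if (nrow(Xi) == 0L)
        stop("taxon ", taxon, " is absent from all samples")
    mean(-(Xi %*% a))
}

#' Half-normal prior draw for the intra-taxa interaction strength
#'
#' When \eqn{a_{ii}} is unknown it is drawn as \eqn{-|v|},
#' \eqn{v \sim N(-1, 0.1^2)}: strictly negative, centered near -1.
#'
#' @param n number of draws.
#' @param mean,sd parameters of the underlying normal.
#' @return numeric vector of strictly negative values.
#' @export
drawAii <- function(n = 1L, mean = -1, sd = 0.1) -abs(rnorm(n, mean, sd))

#' Lasso inference of one GLV row
#'
#' L1-penalized fit of the row regression
#' \eqn{-a_{ii} x_i = \sum_{j \ne i} a_{ij} x_j + r_i} with the penalty
#' chosen by k-fold cross-validation (\code{lambda.min}), assuming a sparse
#' interaction matrix.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param taxon integer(1) taxon index.
#' @param aii numeric(1) < 0, known or drawn intra-taxa strength.
#' @param folds cross-validation folds (default 10).
#' @param nlambda size of the logarithmic lambda grid (default 100).
#' @param lambda optional fixed penalty; 0 reduces to the least-squares
#'   hyperplane fit.
#' @param refit re-estimate the selected coefficients by ordinary least
#'   squares (the "relaxed" Lasso), removing the L1 shrinkage bias from the
#'   reported strengths while keeping the Lasso-selected support
#'   (default TRUE).
#' @return list with \code{a} (sparse full-length row), \code{r}
#'   (intercept/growth-rate estimate) and \code{lambda} (selected penalty).
#' @export
lassoInferRow <- function(samples, taxon, aii = -1, folds = 10L,
                          nlambda = 100L, lambda = NULL, refit = TRUE) {
    d <- rowDesign(samples, taxon)
    y <- d$y * (-aii)
    a <- numeric(nTaxa(samples))
    a[taxon] <- aii
    keep <- which(apply(d$X, 2L, sd) > 0)
    if (length(keep) == 0L)
        return(list(a = a, r = mean(y), lambda = NA_real_))
    X <- d$X[, keep, drop = FALSE]
    if (!is.null(lambda) && length(lambda) == 1L && lambda == 0) {
        fit <- lm(y ~ X)
        cf <- coef(fit)
        a[d$predictors[keep]] <- cf[-1L]
        return(list(a = a, r = unname(cf[1L]), lambda = 0))
    }
    if (is.null(lambda)) {
        cv <- glmnet::cv.glmnet(X, y, nfolds = folds, nlambda = nlambda)
        lam <- cv$lambda.min
        fit <- cv$glmnet.fit
    } else {
        fit <- glmnet::glmnet(X, y, nlambda = nlambda)
        lam <- lambda
    }
    cf <- as.numeric(coef(fit, s = lam))
    sel <- which(cf[-1L] != 0)
    if (refit && length(sel) > 0L && length(sel) < nrow(X)) {
        ols <- lm(y ~ X[, sel, drop = FALSE])
        cfo <- coef(ols)
        if (!anyNA(cfo)) {
            a[d$predictors[keep][sel]] <- cfo[-1L]
            return(list(a = a, r = unname(cfo[1L]), lambda = lam))
        }
    }
    a[d$predictors[keep]] <- cf[-1L]
    list(a = a, r = cf[1L], lambda = lam)
}

#' Infer GLV interaction strengths and growth rates from steady-state data
#'
#' Full-matrix orchestration: per taxon, a GLV consistency check
#' (\code{\link{glvConsistency}}), then row inference by the chosen method
#' (\code{"exact"} least squares with a known pinned \eqn{a_{ii}},
#' cross-validated \code{"lasso"}, or \code{"knockoff"}-filtered Lasso at
#' FDR level \code{q}), and finally growth-rate estimation.  Rows with
#' \eqn{R^2} below \code{r2Threshold} are flagged GLV-inconsistent; for
#' such data only interaction types should be trusted (see
#' \code{\link{inferSignMatrix}}).
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param method \code{"exact"}, \code{"lasso"} or \code{"knockoff"}.
#' @param aii either a numeric scalar/vector of known intra-taxa strengths,
#'   or \code{"halfnormal"} to draw each row's \eqn{a_{ii}} from
#'   \eqn{-|N(-1, 0.1^2)|}.
#' @param q knockoff FDR level (default 0.2).
#' @param folds CV folds for the Lasso (default 10).
#' @param average average replicate samples sharing a support (default
#'   TRUE).
#' @param r2Threshold GLV-consistency flag threshold (default 0.9).
#' @return a \linkS4class{GLVFit}.
#' @examples
#' mod <- randomNetwork(6, connectivity = 0.5)
#' x <- generateSampleSet(mod, omega = 30, presence = "uniform")
#' fit <- inferGLV(x, method = "exact", aii = -1)
#' max(abs(interactionMatrix(fit) - mod@A))
#' @export
inferGLV <- function(samples, method = c("exact", "lasso", "knockoff"),
                     aii = -1, q = 0.2, folds = 10L, average = TRUE,
                     r2Threshold = 0.9) {
    method <- match.arg(method)
    if (average)
        samples <- averageReplicates(samples)
    N <- nTaxa(samples)
    halfnormal <- identical(aii, "halfnormal")
    if (!halfnormal) {
        aii <- rep_len(as.numeric(aii), N)
        if (any(aii >= 0)) stop("pinned aii values must be negative")
    }
    A <- matrix(0, N, N, dimnames = list(colnames(abundances(samples)),
                                         colnames(abundances(samples))))
    r <- numeric(N)
    diagn <- data.frame(taxon = seq_len(N), r_squared = NA_real_,
                       n_samples = NA_integer_, n_selected = NA_integer_,
                       glv_consistent = NA, underdetermined = NA)
    aiiUsed <- numeric(N)
    for (i in seq_len(N)) {
        cons <- glvConsistency(samples, i)
        diagn$r_squared[i] <- cons$r_squared
        diagn$n_samples[i] <- cons$n_samples
        diagn$underdetermined[i] <- cons$underdetermined
        diagn$glv_consistent[i] <- !is.na(cons$r_squared) &&
            cons$r_squared >= r2Threshold
        ai <- if (halfnormal) drawAii(1L) else aii[i]
        aiiUsed[i] <- ai
        res <- tryCatch(switch(method,
            exact = {
                f <- fitRowExact(samples, i, aii = ai)
                list(a = f$a, r = estimateGrowthRate(f$a, samples, i),
                     nsel = sum(f$a[-i] != 0))
            },
            lasso = {
                f <- lassoInferRow(samples, i, aii = ai, folds = folds)
                list(a = f$a, r = f$r, nsel = sum(f$a[-i] != 0))
            },
            knockoff = {
                f <- knockoffFilterRow(samples, i, q = q, aii = ai)
                list(a = f$a, r = f$r, nsel = length(f$selected))
            }), error = function(e) {
                warning("taxon ", i, ": ", conditionMessage(e),
                        " (row left undetermined)")
                NULL
            })
        if (is.null(res)) {
            A[i, ] <- NA_real_
            r[i] <- NA_real_
            diagn$underdetermined[i] <- TRUE
            next
        }
        A[i, ] <- res$a
        r[i] <- res$r
        diagn$n_selected[i] <- res$nsel
    }
    new("GLVFit", A = A, r = r, diagnostics = diagn, method = method,
        parameters = list(aii = if (halfnormal) "halfnormal" else aii,
                          aiiUsed = aiiUsed, q = q, folds = folds,
                          r2Threshold = r2Threshold))
}

#' Normalized root-mean-square error of a GLV fit
#'
#' Root-mean-square error of the inferred versus true parameters,
#' normalized per the standard NRMSE definition by the range
#' (\eqn{\max - \min}) of the true values: computed over the full
#' interaction matrix for \eqn{A} and over the growth-rate vector for
#' \eqn{r}.  \code{normalization = "frobenius"} instead returns the
#' Frobenius-relative error over off-diagonal entries (a scale-free
#' alternative, typically an order of magnitude larger for sparse weak
#' interaction matrices).
#'
#' @param fit a \linkS4class{GLVFit} (or a numeric matrix).
#' @param trueA true interaction matrix.
#' @param trueR true growth-rate vector (optional).
#' @param normalization \code{"range"} (default) or \code{"frobenius"}.
#' @return list with \code{nrmse_A} and (when \code{trueR} given)
#'   \code{nrmse_r}.
#' @export
glvNRMSE <- function(fit, trueA, trueR = NULL,
                     normalization = c("range", "frobenius")) {
    normalization <- match.arg(normalization)
    A <- if (is(fit, "GLVFit")) interactionMatrix(fit) else as.matrix(fit)
    rhat <- if (is(fit, "GLVFit")) growthRates(fit) else NULL
    if (normalization == "range") {
        out <- list(nrmse_A = sqrt(mean((A - trueA)^2)) /
                        (max(trueA) - min(trueA)))
        if (!is.null(trueR)) {
            if (is.null(rhat)) stop("need a GLVFit to score growth rates")
            rng <- max(trueR) - min(trueR)
            if (rng == 0) rng <- max(abs(trueR), 1)
            out$nrmse_r <- sqrt(mean((rhat - trueR)^2)) / rng
            ## single error number over all inferred parameters (A and r
            ## together), normalized by the range of the true parameter set
            theta <- c(trueA, trueR)
            thetaHat <- c(A, rhat)
            out$nrmse_all <- sqrt(mean((thetaHat - theta)^2)) /
                (max(theta) - min(theta))
        }
    } else {
        off <- row(trueA) != col(trueA)
        out <- list(nrmse_A = sqrt(sum((A[off] - trueA[off])^2)) /
                        sqrt(sum(trueA[off]^2)))
        if (!is.null(trueR)) {
            if (is.null(rhat)) stop("need a GLVFit to score growth rates")
            out$nrmse_r <- sqrt(sum((rhat - trueR)^2)) / sqrt(sum(trueR^2))
        }
    }
    out
}
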