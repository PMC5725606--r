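## Synthetic community generator: random directed interaction networks,
## four population-dynamics models, steady states on random taxon-presence
## supports, and the multiplicative uniform measurement-noise model.

#' Random directed ecological interaction network
#'
#' Each off-diagonal weight \eqn{a_{ij}} is non-zero independently with
#' probability \code{connectivity}; non-zero weights are drawn from
#' \code{weightDist} and the diagonal is fixed at \code{diagValue}
#' (self-limitation).  The default weight distribution is uniform on
#' \eqn{\pm[0.2, 1]} scaled by \eqn{0.35/\sqrt{N \cdot connectivity}}: a
#' May-style stability margin that keeps random communities linearly stable,
#' makes restricted equilibria frequently feasible (so taxon pairs broadly
#' coexist across random supports rather than excluding each other), and
#' still leaves inter-taxa interactions strong enough to be identified
#' against measurement noise.
#'
#' @param N integer(1) number of taxa.
#' @param connectivity numeric(1) in (0, 1], probability of a directed edge.
#' @param weightDist function(n) returning n non-zero weights; NULL for the
#'   default described above.
#' @param diagValue numeric(1) < 0, intra-taxa interaction strength
#'   (default -1).
#' @param kind dynamics kind for the returned model (default "glv").
#' @param c,d saturation parameters for the non-GLV kinds (default 0.1).
#' @param r growth-rate vector; NULL draws \eqn{r_i \sim U[0.1, 1]}.
#' @return a \linkS4class{CommunityModel}.
#' @export
randomNetwork <- function(N, connectivity = 0.4, weightDist = NULL,
                          diagValue = -1, kind = "glv", c = 0.1, d = 0.1,
                          r = NULL) {
    if (connectivity <= 0 || connectivity > 1)
        stop("connectivity must be in (0, 1]")
    if (is.null(weightDist)) {
        scale <- 0.35 / sqrt(N * connectivity)
        weightDist <- function(n)
            sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.2, 1) * scale
    }
    A <- matrix(0, N, N)
    off <- which(row(A) != col(A))
    edge <- off[runif(length(off)) < connectivity]
    A[edge] <- weightDist(length(edge))
    diag(A) <- diagValue
    if (is.null(r)) r <- runif(N, 0.1, 1)
    new("CommunityModel", kind = kind, A = A, r = as.numeric(r),
        c = c, d = d)
}

#' Construct a community model from explicit parameters
#'
#' @param A interaction weight matrix (negative diagonal).
#' @param r growth-rate vector.
#' @param kind one of \code{"glv"}, \code{"holling2"}, \code{"db"},
#'   \code{"cm"}.
#' @param c,d saturation parameters (default 0.1).
#' @return a \linkS4class{CommunityModel}.
#' @export
communityModel <- function(A, r, kind = "glv", c = 0.1, d = 0.1) {
    new("CommunityModel", kind = kind, A = as.matrix(A), r = as.numeric(r),
        c = c, d = d)
}

## per-capita growth f(x) for the four dynamics kinds (vectorized over taxa)
percapGrowth <- function(model, x) {
    A <- model@A; r <- model@r
    switch(model@kind,
        glv = r + as.vector(A %*% x),
        holling2 = r + as.vector(A %*% (x / (1 + model@c * x))),
        db = {
            g <- outer(model@d * x, model@c * x, "+") + 1  # [i,j] = 1+c x_j+d x_i
            r + rowSums(A * rep(x, each = length(x)) / g)
        },
        cm = {
            sat <- x / (1 + model@c * x)
            r + as.vector(A %*% sat) / (1 + model@d * x)
        })
}

## full RHS dx/dt = x * f(x)
communityRHS <- function(model, x) x * percapGrowth(model, x)

#' Ground-truth interaction-sign matrix of a model
#'
#' For all four dynamics kinds the off-diagonal Jacobian entries
#' \eqn{\partial f_i/\partial x_j} keep the sign of \eqn{a_{ij}} throughout
#' the positive orthant (for GLV the Jacobian of \eqn{f} is \eqn{A} itself);
#' the diagonal sign is that of \eqn{a_{ii}}, i.e. negative.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @return integer matrix over \{-1,0,1\}.
#' @rdname jacobianSignTruth
#' @export
setMethod("jacobianSignTruth", "CommunityModel", function(model) {
    s <- sign(model@A)
    storage.mode(s) <- "integer"
    s
})

#' Numerical Jacobian of the per-capita growth functions
#'
#' Central finite differences of \eqn{f(x)}; used to verify that the sign
#' pattern is constant over the positive orthant for the saturating models.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param x positive state vector.
#' @param h relative step (default 1e-6).
#' @return numeric N x N matrix of \eqn{\partial f_i / \partial x_j}.
#' @export
numericJacobian <- function(model, x, h = 1e-6) {
    N <- length(x)
    J <- matrix(0, N, N)
    for (j in seq_len(N)) {
        dx <- h * max(abs(x[j]), 1)
        xp <- x; xp[j] <- x[j] + dx
        xm <- x; xm[j] <- x[j] - dx
        J[, j] <- (percapGrowth(model, xp) - percapGrowth(model, xm)) / (2 * dx)
    }
    J
}

#' Steady state of a GLV model on a taxon support
#'
#' Solves \eqn{A_s x_s = -r_s} for the taxa in \code{support} (all other
#' taxa fixed at zero).  The state is accepted only if it is feasible (all
#' supported abundances strictly positive) and, when \code{checkStability},
#' linearly stable: all eigenvalues of the community Jacobian
#' \eqn{diag(x_s) A_s} have negative real part.
#'
#' @param model a \linkS4class{CommunityModel} of kind \code{"glv"}.
#' @param support integer vector of present-taxon indices.
#' @param checkStability logical(1), default TRUE.
#' @param ... unused.
#' @return full-length abundance vector (zeros off support), or \code{NULL}
#'   when the support admits no feasible stable steady state.
#' @rdname steadyState
#' @export
setMethod("steadyState", "CommunityModel", function(model, support,
                                                    checkStability = TRUE,
                                                    ...) {
    if (model@kind != "glv")
        stop("closed-form steady states exist only for kind 'glv'; use ",
             "integrateToSteadyState() for saturating models")
    support <- sort(unique(as.integer(support)))
    N <- length(model@r)
    stopifnot(all(support >= 1L), all(support <= N), length(support) >= 1L)
    As <- model@A[support, support, drop = FALSE]
    xs <- tryCatch(solve(As, -model@r[support]), error = function(e) NULL)
    if (is.null(xs) || any(!is.finite(xs)) || any(xs <= 0))
        return(NULL)
    if (checkStability) {
        ev <- eigen(diag(xs, nrow = length(xs)) %*% As,
                    only.values = TRUE)$values
        if (any(Re(ev) >= 0)) return(NULL)
    }
    x <- numeric(N)
    x[support] <- xs
    x
})

#' Integrate community dynamics to a steady state
#'
#' Integrates \eqn{dx_i/dt = x_i f_i(x)} from a random positive initial
#' condition on the support until \eqn{\max_i |dx_i/dt| <} \code{tol}
#' (off-support taxa are clamped at zero, which the dynamics preserve).
#' Works for all four kinds; for GLV it agrees with the closed-form
#' \code{\link{steadyState}} solve.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param support integer vector of present-taxon indices.
#' @param x0 optional initial state on the support (default
#'   \eqn{U[0.1, 1]} per supported taxon).
#' @param tol steady-state tolerance on the residual (default 1e-9).
#' @param tMax maximum integration time (default 1e5).
#' @param rtol,atol integrator tolerances.
#' @return full-length abundance vector, or \code{NULL} on non-convergence
#'   or when a supported taxon goes extinct (the trajectory leaves the
#'   support's interior).
#' @export
integrateToSteadyState <- function(model, support, x0 = NULL, tol = 1e-9,
                                   tMax = 1e5, rtol = 1e-9, atol = 1e-11) {
    support <- sort(unique(as.integer(support)))
    N <- length(model@r)
    x <- numeric(N)
    x[support] <- if (is.null(x0)) runif(length(support), 0.1, 1) else x0
    deriv <- function(t, y, parms) {
        y[y < 0] <- 0
        dy <- communityRHS(model, y)
        dy[-support] <- 0
        list(dy)
    }
    tEnd <- 10
    while (tEnd <= tMax) {
        sol <- tryCatch(
            deSolve::ode(y = x, times = c(0, tEnd), func = deriv,
                         parms = NULL, method = "lsoda",
                         rtol = rtol, atol = atol),
            warning = function(w) NULL, error = function(e) NULL)
        if (is.null(sol) || nrow(sol) < 2L) return(NULL)
        x <- pmax(as.numeric(sol[nrow(sol), -1L]), 0)
        if (any(x[support] <= 1e-7)) return(NULL)  # extinction within support
        res <- communityRHS(model, x)
        res[-support] <- 0
        if (max(abs(res)) < tol) return(x)
        tEnd <- tEnd * 4
    }
    NULL
}

#' Draw a random taxon-presence support
#'
#' Under the \code{"uniform"} pattern every taxon is present independently
#' with probability 0.5; under \code{"heterogeneous"} a few taxa (25\%,
#' rounded up) are common (probability 0.9) and the rest rare (probability
#' 0.3), emulating skewed presence frequencies of host-associated
#' communities.  A numeric vector of per-taxon probabilities can be given
#' instead.  Empty draws are redrawn.
#'
#' @param N number of taxa.
#' @param presence \code{"uniform"}, \code{"heterogeneous"}, or numeric(N)
#'   of presence probabilities.
#' @return integer vector of present-taxon indices.
#' @export
drawSupport <- function(N, presence = "uniform") {
    probs <- presenceProbabilities(N, presence)
    repeat {
        s <- which(runif(N) < probs)
        if (length(s) > 0L) return(s)
    }
}

presenceProbabilities <- function(N, presence) {
    if (is.numeric(presence)) {
        stopifnot(length(presence) == N, all(presence >= 0), all(presence <= 1))
        return(presence)
    }
    switch(match.arg(presence, c("uniform", "heterogeneous")),
        uniform = rep(0.5, N),
        heterogeneous = {
            nCommon <- ceiling(0.25 * N)
            c(rep(0.9, nCommon), rep(0.3, N - nCommon))
        })
}

#' Generate a steady-state sample set from a community model
#'
#' Repeatedly draws taxon-presence supports from the presence model,
#' computes the steady state restricted to each support (closed-form solve
#' for GLV, numerical integration otherwise), and collects \code{omega}
#' feasible steady states with pairwise-distinct supports.  Duplicate
#' supports and infeasible/unstable supports are rejected and counted.
#'
#' @param model a \linkS4class{CommunityModel}.
#' @param omega integer(1) >= 1, number of samples to collect.
#' @param presence forwarded to \code{\link{drawSupport}}.
#' @param maxDraws draw budget (default \code{500 * omega}).
#' @param strict error when the budget is exhausted before \code{omega}
#'   distinct feasible supports are found (default TRUE); with
#'   \code{strict = FALSE} the samples found so far are returned with a
#'   warning.
#' @param zeroTol zero threshold of the returned object.
#' @return a \linkS4class{SteadyStateSamples}; attribute \code{"rejections"}
#'   records the counts of duplicate and infeasible draws.
#' @export
generateSampleSet <- function(model, omega, presence = "uniform",
                              maxDraws = 500L * omega, strict = TRUE,
                              zeroTol = 1e-8) {
    stopifnot(omega >= 1L)
    N <- length(model@r)
    if (omega > maxSupportCount(N))
        stop("omega exceeds the number of possible supports 2^N - 1 = ",
             maxSupportCount(N))
    seen <- character(0)
    out <- matrix(0, nrow = 0, ncol = N)
    rej <- c(duplicate = 0L, infeasible = 0L)
    draws <- 0L
    while (nrow(out) < omega && draws < maxDraws) {
        draws <- draws + 1L
        s <- drawSupport(N, presence)
        key <- paste(s, collapse = ",")
        if (key %in% seen) {
            rej["duplicate"] <- rej["duplicate"] + 1L
            next
        }
        x <- if (model@kind == "glv") steadyState(model, s)
             else integrateToSteadyState(model, s)
        if (is.null(x)) {
            rej["infeasible"] <- rej["infeasible"] + 1L
            seen <- c(seen, key)          # support settled as infeasible
            next
        }
        seen <- c(seen, key)
        out <- rbind(out, x)
    }
    if (nrow(out) < omega) {
        msg <- paste0("only ", nrow(out), " of ", omega,
                      " feasible distinct supports found within the draw budget")
        if (strict) stop(msg) else warning(msg)
        if (nrow(out) == 0L) stop("no feasible supports found")
    }
    rownames(out) <- paste0("sample_", seq_len(nrow(out)))
    res <- SteadyStateSamples(out, zeroTol = zeroTol)
    attr(res, "rejections") <- rej
    res
}

#' Add multiplicative uniform measurement noise
#'
#' Each non-zero abundance \eqn{x} is independently replaced by
#' \eqn{x + \eta u} with \eqn{u \sim U[-x, x]}; zeros (absent taxa) are
#' untouched.  For \eqn{\eta \le 1} the perturbed abundances remain
#' non-negative.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param eta numeric(1) >= 0, noise level.
#' @return a \linkS4class{SteadyStateSamples} with perturbed abundances.
#' @export
addNoise <- function(samples, eta) {
    stopifnot(eta >= 0)
    a <- abundances(samples)
    nz <- a > zeroTol(samples)
    u <- runif(sum(nz), -1, 1) * a[nz]
    a[nz] <- a[nz] + eta * u
    SteadyStateSamples(a, zeroTol = zeroTol(samples))
}
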