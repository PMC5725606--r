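#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata
#' @importFrom stats coef lm runif rnorm sd setNames predict
#' @importFrom utils combn head
NULL

#' Container for cross-sectional steady-state abundance samples
#'
#' \code{SteadyStateSamples} holds an \eqn{\Omega \times N} table of absolute
#' abundances (\eqn{\Omega} samples, \eqn{N} taxa) together with the numerical
#' zero threshold used to derive each sample's support (its "taxa collection":
#' the set of taxa with abundance above the threshold).  The class extends
#' \linkS4class{SummarizedExperiment}; the single assay \code{"abundance"}
#' stores taxa in rows and samples in columns, following Bioconductor
#' convention, while all inference code works with the transposed
#' samples-by-taxa orientation returned by \code{\link{abundances}}.
#'
#' Abundances must be non-negative absolute abundances (arbitrary units); a
#' zero means the taxon is absent from that community.  Relative (unit-sum)
#' abundances defeat the inference and are rejected by
#' \code{\link{inferSignMatrix}} (see \code{\link{compositionalityCheck}}).
#'
#' @slot zeroTol numeric(1), abundances at or below this value count as absent.
#'
#' @seealso \code{\link{SteadyStateSamples}} (constructor),
#'   \code{\link{abundances}}, \code{\link{sampleSupports}},
#'   \code{\link{averageReplicates}}
#' @export
setClass("SteadyStateSamples",
    contains = "SummarizedExperiment",
    representation(zeroTol = "numeric"))

setValidity("SteadyStateSamples", function(object) {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (!is.numeric(a))
        return("abundance assay must be numeric")
    if (any(!is.finite(a)))
        return("abundances must be finite")
    if (any(a < 0))
        return("abundances must be non-negative (absolute abundances)")
    if (nrow(a) < 2L)
        return("at least two taxa are required (N >= 2)")
    if (ncol(a) < 1L)
        return("at least one sample is required (Omega >= 1)")
    if (length(object@zeroTol) != 1L || object@zeroTol < 0)
        return("zeroTol must be a single non-negative number")
    TRUE
})

#' Result of interaction-type (sign-pattern) inference
#'
#' Holds the inferred \eqn{N \times N} ternary interaction-type matrix
#' (entries in \{-1, 0, +1\}, \code{NA} marking undetermined signs) plus the
#' per-taxon inference report: candidate sign-pattern sets, confidence scores
#' \eqn{\phi} for the heuristic path, and provenance (method, seed,
#' parameters).
#'
#' @slot signs integer matrix, inferred sign of the Jacobian entry J_ij
#'   (effect of taxon j on taxon i); \code{NA} = undetermined.
#' @slot method character(1), \code{"bruteforce"} or \code{"heuristic"}.
#' @slot phi numeric, per-taxon best confidence score (NA for brute force).
#' @slot candidateCounts integer, per-taxon number of admissible candidate
#'   sign-patterns (brute force) or of tied maximal patterns (heuristic).
#' @slot report list of per-taxon details (candidate patterns, scored lines).
#' @slot parameters list of run parameters (psi, zeroTol, seed, prior).
#' @export
setClass("SignInference",
    representation(signs = "matrix", method = "character", phi = "numeric",
                   candidateCounts = "integer", report = "list",
                   parameters = "list"))

setValidity("SignInference", function(object) {
    s <- object@signs
    if (nrow(s) != ncol(s))
        return("sign matrix must be square")
    ok <- s[!is.na(s)] %in% c(-1L, 0L, 1L)
    if (!all(ok))
        return("sign entries must be -1, 0, +1 or NA")
    TRUE
})

#' Fitted generalized Lotka-Volterra parameters
#'
#' Interaction matrix \eqn{A = (a_{ij})} and intrinsic growth-rate vector
#' \eqn{r} inferred from steady-state samples, with per-row diagnostics:
#' the hyperplane-fit coefficient of determination \eqn{R^2} (the GLV
#' consistency score), sample counts, and the support selected by the
#' knockoff filter where applicable.
#'
#' @slot A numeric matrix, inferred interaction strengths (per-time units).
#' @slot r numeric vector, inferred intrinsic growth rates.
#' @slot diagnostics data.frame with one row per taxon: \code{r_squared},
#'   \code{n_samples}, \code{n_selected}, \code{glv_consistent},
#'   \code{underdetermined}.
#' @slot method character(1): \code{"exact"}, \code{"lasso"} or
#'   \code{"knockoff"}.
#' @slot parameters list of run parameters (aii, q, folds, seed, ...).
#' @export
setClass("GLVFit",
    representation(A = "matrix", r = "numeric", diagnostics = "data.frame",
                   method = "character", parameters = "list"))

#' Parameterized community population-dynamics model
#'
#' A tagged union of the four supported dynamics on \eqn{N} taxa, all of the
#' form \eqn{dx_i/dt = x_i f_i(x)}:
#' \describe{
#'   \item{glv}{\eqn{f_i = r_i + \sum_j a_{ij} x_j}}
#'   \item{holling2}{\eqn{f_i = r_i + \sum_j a_{ij} x_j / (1 + c x_j)}}
#'   \item{db}{(Beddington-DeAngelis)
#'     \eqn{f_i = r_i + \sum_j a_{ij} x_j / (1 + c x_j + d x_i)}}
#'   \item{cm}{(Crowley-Martin)
#'     \eqn{f_i = r_i + \sum_j a_{ij} x_j / ((1 + c x_j)(1 + d x_i))}}
#' }
#' For all four kinds the off-diagonal Jacobian sign equals
#' \eqn{sign(a_{ij})} throughout the positive orthant, so \code{A} doubles as
#' the ground-truth interaction-sign oracle (see
#' \code{\link{jacobianSignTruth}}).
#'
#' @slot kind character(1) in \code{c("glv","holling2","db","cm")}.
#' @slot A numeric matrix of interaction weights (diagonal strictly negative).
#' @slot r numeric vector of intrinsic growth rates.
#' @slot c,d numeric(1), saturation parameters of the non-GLV kinds.
#' @export
setClass("CommunityModel",
    representation(kind = "character", A = "matrix", r = "numeric",
                   c = "numeric", d = "numeric"))

setValidity("CommunityModel", function(object) {
    if (!object@kind %in% c("glv", "holling2", "db", "cm"))
        return("kind must be one of glv, holling2, db, cm")
    if (nrow(object@A) != ncol(object@A))
        return("A must be square")
    if (length(object@r) != nrow(object@A))
        return("length(r) must equal nrow(A)")
    if (any(diag(object@A) >= 0))
        return("diagonal entries of A must be strictly negative")
    if (object@c < 0 || object@d < 0)
        return("saturation parameters c, d must be non-negative")
    TRUE
})
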