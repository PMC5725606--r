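## Readers and writers for sample tables and inference results.

#' Read a steady-state sample table
#'
#' Expects delimited text with samples in rows: a header row of taxon
#' names, the first column holding sample identifiers, and a non-negative
#' numeric body of absolute abundances (zeros mean absent).  Tables with
#' taxa in rows can be read with \code{transpose = TRUE}.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param transpose the file stores taxa in rows (default FALSE).
#' @param average average replicate samples sharing a support
#'   (default FALSE).
#' @param zeroTol zero threshold of the returned object.
#' @return a \linkS4class{SteadyStateSamples}.
#' @export
readSampleTable <- function(path, sep = "\t", transpose = FALSE,
                            average = FALSE, zeroTol = 1e-8) {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            row.names = 1L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m))
        stop("sample table body must be numeric")
    if (transpose) m <- t(m)
    if (any(!is.finite(m)))
        stop("sample table contains missing or non-finite abundances")
    if (any(m < 0))
        stop("negative abundances found; absolute abundances must be >= 0")
    x <- SteadyStateSamples(m, zeroTol = zeroTol)
    if (average) x <- averageReplicates(x)
    x
}

#' Read a prior-knowledge file of interaction signs
#'
#' Three delimited columns: taxon_i, taxon_j, sign (in -1/0/1).  Taxa may
#' be given as indices or as names matching \code{taxonNames}.
#'
#' @param path file path.
#' @param taxonNames character vector of taxon names defining the matrix
#'   order.
#' @param sep field separator (default tab).
#' @return integer N x N matrix over \{-1,0,1,NA\} usable as the
#'   \code{prior} of \code{\link{inferSignMatrix}}.
#' @export
readPriorFile <- function(path, taxonNames, sep = "\t") {
    df <- utils::read.table(path, header = FALSE, sep = sep,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
        stop("prior file needs three columns: taxon_i, taxon_j, sign")
    N <- length(taxonNames)
    prior <- matrix(NA_integer_, N, N,
                    dimnames = list(taxonNames, taxonNames))
    toIdx <- function(v) {
        idx <- suppressWarnings(as.integer(v))
        named <- match(as.character(v), taxonNames)
        out <- ifelse(is.na(idx), named, idx)
        if (any(is.na(out))) stop("unknown taxon in prior file")
        out
    }
    i <- toIdx(df[[1L]]); j <- toIdx(df[[2L]])
    s <- as.integer(df[[3L]])
    if (any(!s %in% c(-1L, 0L, 1L)))
        stop("prior signs must be -1, 0 or 1")
    prior[cbind(i, j)] <- s
    prior
}

#' Write sign-inference results
#'
#' Writes \code{<prefix>_signs.tsv} (the ternary matrix, \code{NA} spelled
#' literally), \code{<prefix>_edges.tsv} (i, j, sign for determined
#' non-zero entries) and \code{<prefix>_report.json} (method, parameters,
#' per-taxon candidate counts and confidence).
#'
#' @param x a \linkS4class{SignInference}.
#' @param prefix output path prefix.
#' @return invisibly, the vector of written paths.
#' @export
writeSignResults <- function(x, prefix) {
    s <- signMatrix(x)
    pSigns <- paste0(prefix, "_signs.tsv")
    utils::write.table(s, pSigns, sep = "\t", quote = FALSE, na = "NA")
    idx <- which(!is.na(s) & s != 0L, arr.ind = TRUE)
    edges <- data.frame(i = idx[, 1L], j = idx[, 2L], sign = s[idx])
    pEdges <- paste0(prefix, "_edges.tsv")
    utils::write.table(edges, pEdges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rep <- list(method = x@method, parameters = x@parameters,
                phi = x@phi, candidate_counts = x@candidateCounts,
                undetermined = sum(is.na(s)))
    pJson <- paste0(prefix, "_report.json")
    jsonlite::write_json(rep, pJson, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(c(pSigns, pEdges, pJson))
}

#' Write GLV-fit results
#'
#' Writes \code{<prefix>_A.tsv}, \code{<prefix>_r.tsv},
#' \code{<prefix>_edges.tsv} (i, j, a_ij for non-zero off-diagonal
#' entries) and \code{<prefix>_manifest.json} with method, parameters and
#' per-row diagnostics.
#'
#' @param x a \linkS4class{GLVFit}.
#' @param prefix output path prefix.
#' @return invisibly, the vector of written paths.
#' @export
writeGLVResults <- function(x, prefix) {
    A <- interactionMatrix(x)
    pA <- paste0(prefix, "_A.tsv")
    utils::write.table(A, pA, sep = "\t", quote = FALSE)
    pR <- paste0(prefix, "_r.tsv")
    utils::write.table(data.frame(taxon = seq_along(growthRates(x)),
                                  r = growthRates(x)),
                       pR, sep = "\t", quote = FALSE, row.names = FALSE)
    idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
    edges <- data.frame(i = idx[, 1L], j = idx[, 2L], a_ij = A[idx])
    pE <- paste0(prefix, "_edges.tsv")
    utils::write.table(edges, pE, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    man <- list(method = x@method, parameters = x@parameters,
                diagnostics = rowDiagnostics(x))
    pJ <- paste0(prefix, "_manifest.json")
    jsonlite::write_json(man, pJ, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(c(pA, pR, pE, pJ))
}
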