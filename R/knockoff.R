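## Fixed-X equi-correlated knockoffs with the Lasso signed-max statistic and
## the knockoff+ threshold (the original fixed-design knockoff filter).
## Self-contained construction on top of base linear algebra + glmnet.

## Build equi-correlated fixed-X knockoffs for an n x p design whose columns
## have been centered and scaled to unit L2 norm. Requires n >= 2p.
knockoffConstruct <- function(X) {
    n <- nrow(X); p <- ncol(X)
    if (n < 2L * p)
        stop("fixed-X knockoff construction needs n >= 2p (have n = ", n,
             ", p = ", p, ")")
    G <- crossprod(X)                  # Gram matrix, unit diagonal
    eg <- eigen(G, symmetric = TRUE)
    lmin <- min(eg$values)
    if (lmin < 1e-10)
        stop("design Gram matrix is numerically singular; knockoffs not constructible")
    s <- rep(min(2 * lmin, 1) * 0.999, p)  # equi-correlated choice, kept PSD
    Ginv <- eg$vectors %*% (t(eg$vectors) / eg$values)
    SG <- diag(s, p)
    C2 <- 2 * SG - SG %*% Ginv %*% SG
    C2 <- (C2 + t(C2)) / 2
    ec <- eigen(C2, symmetric = TRUE)
    C <- diag(sqrt(pmax(ec$values, 0)), p) %*% t(ec$vectors)
    ## orthonormal basis of the complement of col(X) within R^n (p columns)
    Qfull <- qr.Q(qr(X), complete = TRUE)
    U <- Qfull[, (p + 1L):(2L * p), drop = FALSE]
    Xk <- X %*% (diag(p) - Ginv %*% SG) + U %*% C
    list(Xk = Xk, s = s)
}

## Lasso signed-max lambda statistics: Z_j = largest lambda at which
## variable j enters the lasso path on the augmented design [X, Xk].
## W_j = max(Z_j, Zk_j) * sign(Z_j - Zk_j).
knockoffStatistics <- function(X, Xk, y, nlambda = 200L) {
    p <- ncol(X)
    fit <- glmnet::glmnet(cbind(X, Xk), y, intercept = FALSE,
                          standardize = FALSE, nlambda = nlambda,
                          lambda.min.ratio = 1e-4)
    beta <- fit$beta                   # (2p) x nlambda sparse matrix
    lam <- fit$lambda
    entry <- apply(as.matrix(beta) != 0, 1L, function(nz)
        if (any(nz)) max(lam[nz]) else 0)
    Z <- entry[seq_len(p)]
    Zk <- entry[p + seq_len(p)]
    pmax(Z, Zk) * sign(Z - Zk)
}

## knockoff+ threshold at FDR level q
knockoffThreshold <- function(W, q) {
    ts <- sort(unique(abs(W[W != 0])))
    for (t in ts) {
        fdp <- (1 + sum(W <= -t)) / max(1, sum(W >= t))
        if (fdp <= q) return(t)
    }
    Inf
}

#' Knockoff-filtered selection for one GLV row
#'
#' Applies the fixed-X equi-correlated knockoff filter to the row
#' regression \eqn{-a_{ii} x_i = \sum_{j \ne i} a_{ij} x_j + r_i} over the
#' samples containing taxon \eqn{i}, selecting a set of inter-taxa
#' interactions whose expected false-discovery proportion is controlled at
#' level \eqn{q} (knockoff+ threshold).  Coefficients of the selected
#' support are then re-fitted by ordinary least squares.
#'
#' @param samples a \linkS4class{SteadyStateSamples} object.
#' @param taxon integer(1) taxon index.
#' @param q numeric(1) in (0, 1), target false-discovery rate.
#' @param aii numeric(1) < 0, the intra-taxa interaction strength used to
#'   scale the response (known value or a half-normal draw).
#' @return list with \code{a} (full-length inferred row, \code{a[taxon]
#'   = aii}), \code{r} (intercept, i.e. the growth-rate estimate),
#'   \code{selected} (taxon indices of selected inter-taxa interactions)
#'   and \code{fallback} (TRUE when the knockoff construction was
#'   infeasible and the unfiltered Lasso row was returned instead).
#' @export
knockoffFilterRow <- function(samples, taxon, q = 0.2, aii = -1) {
    if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
        stop("q must be a single number strictly between 0 and 1")
    d <- rowDesign(samples, taxon)
    Xs <- scale(d$X, center = TRUE, scale = FALSE)
    norms <- sqrt(colSums(Xs^2))
    usable <- which(norms > 1e-10)
    yc <- d$y * (-aii)
    yc <- yc - mean(yc)
    sel <- integer(0)
    fallback <- FALSE
    if (length(usable) == 0L) {
        sel <- integer(0)
    } else {
        Xn <- sweep(Xs[, usable, drop = FALSE], 2L, norms[usable], "/")
        p <- ncol(Xn); n <- nrow(Xn)
        if (n < 2L * p && n >= p + 2L) {
            ## standard augmentation: pad the design with zero rows and the
            ## response with N(0, sigma^2) draws, sigma estimated from the
            ## full-model residuals, so that n >= 2p holds by construction
            sigma <- sqrt(sum(stats::lm.fit(Xn, yc)$residuals^2) / (n - p - 1L))
            extra <- 2L * p - n
            Xn <- rbind(Xn, matrix(0, extra, p))
            yc <- c(yc, rnorm(extra, 0, sigma))
        }
        kn <- tryCatch(knockoffConstruct(Xn), error = function(e) e)
        if (inherits(kn, "error")) {
            warning("knockoff construction infeasible (",
                    conditionMessage(kn),
                    "); returning unfiltered Lasso selection")
            fallback <- TRUE
            las <- lassoInferRow(samples, taxon, aii = aii)
            return(list(a = las$a, r = las$r,
                        selected = which(las$a != 0 &
                                         seq_along(las$a) != taxon),
                        fallback = TRUE))
        }
        W <- knockoffStatistics(Xn, kn$Xk, yc)
        thr <- knockoffThreshold(W, q)
        sel <- usable[W >= thr & W > 0]
    }
    ## OLS refit on the selected support (original scale, with intercept)
    a <- numeric(nTaxa(samples))
    a[taxon] <- aii
    if (length(sel) > 0L) {
        df <- data.frame(y = d$y * (-aii), d$X[, sel, drop = FALSE])
        fit <- lm(y ~ ., data = df)
        cf <- coef(fit)
        a[d$predictors[sel]] <- cf[-1L]
        r <- unname(cf[1L])
    } else {
        r <- mean(d$y * (-aii))
    }
    list(a = a, r = r, selected = d$predictors[sel], fallback = fallback)
}
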