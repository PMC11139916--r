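## Negative binomial GLM engine: ridge-penalized weighted IRLS, Cox-Reid
## dispersion profiling, likelihood-ratio test, BH adjustment.

.PHI_MIN <- 1e-8
.PHI_MAX <- 10
.ETA_CLIP <- 50

#' Weighted NB log-likelihood
#' @keywords internal
#' @noRd
.nbLogLik <- function(y, mu, phi, w) {
    size <- 1 / max(phi, .PHI_MIN)
    sum(w * dnbinom(y, size = size, mu = mu, log = TRUE))
}

#' Fit a ridge-penalized weighted negative binomial GLM
#'
#' Maximizes sum_i w_i * l_NB(y_i; mu_i, phi) - (lambda/2) * ||beta_-0||^2
#' with log mu_i = x_i' beta + offset_i, by Fisher-scoring IRLS with
#' step-halving on the penalized log-likelihood. The intercept column
#' (named \code{"(Intercept)"} or constant) is not penalized. The ridge
#' keeps coefficients finite under perfect separation (group-wise
#' structured zeros) where unpenalized ML diverges.
#'
#' @param y non-negative integer response vector.
#' @param X design matrix (n x p, full column rank).
#' @param offset per-observation log offset (log size factors); default 0.
#' @param weights per-observation weights in [0,1]; default 1.
#' @param phi fixed NB dispersion (>= 0; 0 treated as Poisson limit).
#' @param ridge penalty lambda >= 0 (default 1e-6).
#' @param maxit,tol IRLS iteration cap and relative tolerance on the
#'   penalized log-likelihood.
#' @param betaStart optional warm start.
#' @return list with \code{beta}, \code{mu}, \code{loglik} (penalized),
#'   \code{loglikUnpen}, \code{converged}, \code{iter}.
#' @export
fitNbGlm <- function(y, X, offset = NULL, weights = NULL, phi,
                     ridge = 1e-6, maxit = 100L, tol = 1e-10,
                     betaStart = NULL) {
    X <- as.matrix(X)
    n <- length(y); p <- ncol(X)
    if (is.null(offset)) offset <- numeric(n)
    if (is.null(weights)) weights <- rep(1, n)
    stopifnot(ridge >= 0, all(weights >= 0), all(weights <= 1 + 1e-12))
    pen <- rep(ridge, p)
    isInt <- apply(X, 2, function(cl) all(cl == cl[1]))
    if (!is.null(colnames(X)) && "(Intercept)" %in% colnames(X))
        isInt <- isInt | colnames(X) == "(Intercept)"
    pen[isInt] <- 0
    phi <- max(phi, 0)
    beta <- if (!is.null(betaStart)) betaStart else {
        z0 <- log(y + 0.5) - offset
        drop(solve(crossprod(X) + diag(1e-8, p), crossprod(X, z0)))
    }
    eta <- pmin(pmax(drop(X %*% beta) + offset, -.ETA_CLIP), .ETA_CLIP)
    mu <- exp(eta)
    pll <- .nbLogLik(y, mu, phi, weights) - 0.5 * sum(pen * beta^2)
    converged <- FALSE
    iter <- 0L
    for (it in seq_len(maxit)) {
        iter <- it
        W <- weights * mu / (1 + phi * mu)
        z <- (eta - offset) + (y - mu) / mu
        A <- crossprod(X, W * X) + diag(pen, p)
        betaNew <- tryCatch(drop(solve(A, crossprod(X, W * z))),
                            error = function(e) beta)
        step <- betaNew - beta
        lam <- 1
        for (h in 1:20) {
            bTry <- beta + lam * step
            etaTry <- pmin(pmax(drop(X %*% bTry) + offset, -.ETA_CLIP),
                           .ETA_CLIP)
            muTry <- exp(etaTry)
            pllTry <- .nbLogLik(y, muTry, phi, weights) -
                0.5 * sum(pen * bTry^2)
            if (is.finite(pllTry) && pllTry >= pll - 1e-12) break
            lam <- lam / 2
        }
        if (!is.finite(pllTry) || pllTry < pll - 1e-12) break
        delta <- pllTry - pll
        beta <- bTry; eta <- etaTry; mu <- muTry; pll <- pllTry
        if (delta < tol * (abs(pll) + 1)) {
            converged <- TRUE
            break
        }
    }
    names(beta) <- colnames(X)
    list(beta = beta, mu = mu, loglik = pll,
         loglikUnpen = .nbLogLik(y, mu, phi, weights),
         converged = converged, iter = iter)
}

#' Cox-Reid adjusted profile log-likelihood in the dispersion
#' @keywords internal
#' @noRd
.crProfile <- function(logphi, y, X, offset, weights, ridge, betaStart) {
    phi <- exp(logphi)
    fit <- fitNbGlm(y, X, offset, weights, phi, ridge, maxit = 50L,
                    tol = 1e-8, betaStart = betaStart)
    W <- weights * fit$mu / (1 + phi * fit$mu)
    XtWX <- crossprod(X, W * X)
    cr <- -0.5 * as.numeric(determinant(XtWX + diag(1e-10, ncol(X)),
                                        logarithm = TRUE)$modulus)
    list(value = fit$loglikUnpen + cr, beta = fit$beta)
}

#' Estimate per-taxon NB dispersions
#'
#' For each taxon, maximizes the Cox-Reid adjusted profile likelihood in
#' phi (beta profiled out by weighted IRLS at each candidate phi), with
#' phi bounded to [1e-8, 10]. An optional empirical-Bayes step shrinks
#' log phi halfway toward a fitted mean-dispersion trend
#' a0 + a1 / baseMean (off by default).
#'
#' @param counts taxa x samples count matrix.
#' @param X design matrix.
#' @param sizeFactors a \linkS4class{SizeFactors} or positive numeric
#'   vector.
#' @param weights optional taxa x samples observation-weight matrix.
#' @param ridge ridge penalty used in the inner fits.
#' @param shrink logical; apply the trend-shrinkage step.
#' @return named numeric vector of dispersions; taxa whose profile is
#'   maximized at the lower bound are returned as exactly 1e-8.
#' @export
estimateDispersion <- function(counts, X, sizeFactors, weights = NULL,
                               ridge = 1e-6, shrink = FALSE) {
    sf <- if (is(sizeFactors, "SizeFactors")) sfValues(sizeFactors)
          else sizeFactors
    offset <- log(sf)
    J <- nrow(counts)
    phi <- numeric(J)
    lo <- log(.PHI_MIN); hi <- log(.PHI_MAX)
    for (j in seq_len(J)) {
        y <- counts[j, ]
        w <- if (is.null(weights)) rep(1, ncol(counts)) else weights[j, ]
        betaStart <- NULL
        f <- function(lp) {
            pr <- .crProfile(lp, y, X, offset, w, ridge, betaStart)
            betaStart <<- pr$beta
            pr$value
        }
        opt <- optimize(f, interval = c(lo, hi), maximum = TRUE,
                        tol = 1e-3)
        lphi <- opt$maximum
        # snap to the bounds when the interior optimum hugs them
        if (lphi < lo + 0.05 && f(lo) >= opt$objective - 1e-8) lphi <- lo
        if (lphi > hi - 0.05 && f(hi) >= opt$objective - 1e-8) lphi <- hi
        phi[j] <- exp(lphi)
    }
    names(phi) <- rownames(counts)
    if (shrink && J >= 3L) {
        baseMean <- rowMeans(sweep(counts, 2, sf, "/"))
        fitTrend <- lm(phi ~ I(1 / baseMean))
        trend <- pmax(fitted(fitTrend), .PHI_MIN)
        phi <- exp(0.5 * log(phi) + 0.5 * log(trend))
        phi <- pmin(pmax(phi, .PHI_MIN), .PHI_MAX)
    }
    phi
}

#' Likelihood-ratio test between nested NB fits
#'
#' stat = max(0, 2 * (loglik_full - loglik_reduced)) referred to a
#' chi-square with df = rank(full) - rank(reduced). Both fits must share
#' the dispersion, offsets, weights and ridge; the penalized
#' log-likelihood difference is used with the unpenalized chi-square
#' reference (the ridge is a numerical stabilizer, not a prior to be
#' tested).
#'
#' @param full,reduced fits from [fitNbGlm()] on nested designs.
#' @param dfFull,dfReduced design ranks; default the coefficient counts.
#' @return list with \code{stat}, \code{df}, \code{pvalue}.
#' @export
lrtNb <- function(full, reduced, dfFull = length(full$beta),
                  dfReduced = length(reduced$beta)) {
    df <- dfFull - dfReduced
    if (df < 0L)
        stop("designs are not nested: the reduced design must be a ",
             "column subspace of the full design")
    stat <- max(0, 2 * (full$loglik - reduced$loglik))
    list(stat = stat, df = df,
         pvalue = if (df == 0L) 1
                  else pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up BH over the non-missing p-values (m = number of non-missing);
#' missing p-values propagate as missing.
#'
#' @param pvalues numeric vector of p-values in [0,1] (NA allowed).
#' @return adjusted p-values in input order.
#' @export
adjustBH <- function(pvalues) {
    out <- rep(NA_real_, length(pvalues))
    ok <- !is.na(pvalues)
    if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
        stop("p-values must lie in [0,1]")
    out[ok] <- p.adjust(pvalues[ok], method = "BH")
    out
}

#' Per-taxon NB LRT over a count table
#'
#' The testing engine shared by both pipeline paths: per taxon, the
#' dispersion is estimated under the full model and held fixed, the full
#' and reduced models are fitted by ridge-penalized (weighted) IRLS with
#' log size-factor offsets, and a likelihood-ratio test compares them.
#'
#' @param counts taxa x samples count matrix.
#' @param Xfull,Xreduced nested design matrices (reduced columns must be
#'   a subset of the full columns, matched by name).
#' @param sizeFactors a \linkS4class{SizeFactors} or positive vector.
#' @param weights optional taxa x samples observation weights.
#' @param ridge ridge penalty (default 1e-6).
#' @param phi optional fixed per-taxon dispersions (skips estimation).
#' @param shrink passed to [estimateDispersion()].
#' @return \code{data.frame} with \code{taxon_id}, \code{base_mean}
#'   (mean of counts / size factor), \code{log2fc} (tested coefficient /
#'   log 2), \code{stat}, \code{df}, \code{pvalue}.
#' @export
nbTestTaxa <- function(counts, Xfull, Xreduced, sizeFactors,
                       weights = NULL, ridge = 1e-6, phi = NULL,
                       shrink = FALSE) {
    Xfull <- as.matrix(Xfull); Xreduced <- as.matrix(Xreduced)
    if (!all(colnames(Xreduced) %in% colnames(Xfull)))
        stop("designs are not nested: reduced columns ",
             paste(setdiff(colnames(Xreduced), colnames(Xfull)),
                   collapse = ", "), " absent from the full design")
    dropped <- setdiff(colnames(Xfull), colnames(Xreduced))
    sf <- if (is(sizeFactors, "SizeFactors")) sfValues(sizeFactors)
          else sizeFactors
    offset <- log(sf)
    if (is.null(phi))
        phi <- estimateDispersion(counts, Xfull, sf, weights, ridge,
                                  shrink)
    J <- nrow(counts)
    out <- data.frame(taxon_id = rownames(counts),
                      base_mean = rowMeans(sweep(counts, 2, sf, "/")),
                      log2fc = NA_real_, stat = NA_real_,
                      df = NA_integer_, pvalue = NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)
    for (j in seq_len(J)) {
        y <- counts[j, ]
        w <- if (is.null(weights)) NULL else weights[j, ]
        full <- fitNbGlm(y, Xfull, offset, w, phi[j], ridge)
        red <- fitNbGlm(y, Xreduced, offset, w, phi[j], ridge)
        lr <- lrtNb(full, red, qr(Xfull)$rank, qr(Xreduced)$rank)
        out$log2fc[j] <- if (length(dropped))
            full$beta[dropped[1]] / log(2) else 0
        out$stat[j] <- lr$stat
        out$df[j] <- lr$df
        out$pvalue[j] <- lr$pvalue
    }
    attr(out, "phi") <- phi
    out
}
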