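## Size-factor normalization: poscounts, TMM, GMPR; log-CPM diagnostics.
## All schemes rescale to geometric mean 1 so the factors act as centred
## log offsets.

.rescaleGeo <- function(s) s / exp(mean(log(s)))

.newSizeFactors <- function(s, ids, method) {
    new("SizeFactors", s = setNames(.rescaleGeo(s), ids), method = method)
}

#' Compute per-sample size factors
#'
#' Dispatches to one of the three schemes. \code{"poscounts"} is a
#' median-of-ratios variant whose per-taxon pseudo-reference is the
#' geometric mean over positive counts only (with divisor = number of
#' samples); \code{"tmm"} is the trimmed mean of M-values; \code{"gmpr"}
#' the geometric mean of pairwise median count ratios. All factors are
#' rescaled to geometric mean 1.
#'
#' @param counts taxa x samples count matrix (or
#'   \linkS4class{MicrobExperiment}).
#' @param method normalization scheme.
#' @param ... passed to the scheme-specific function.
#' @return a \linkS4class{SizeFactors}.
#' @export
computeSizeFactors <- function(counts,
                               method = c("poscounts", "tmm", "gmpr"),
                               ...) {
    method <- match.arg(method)
    if (is(counts, "MicrobExperiment")) counts <- counts(counts)
    switch(method,
           poscounts = sizeFactorsPoscounts(counts, ...),
           tmm = sizeFactorsTMM(counts, ...),
           gmpr = sizeFactorsGMPR(counts, ...))
}

#' Poscounts size factors
#'
#' Per-taxon pseudo-reference g_j = exp( (1/n) * sum over positive counts
#' of log y_ji ) — zeros contribute nothing to the sum but the divisor is
#' the total number of samples n. s_i is the median of y_ji / g_j over
#' taxa with g_j > 0 and y_ji > 0, rescaled to geometric mean 1.
#'
#' @param counts taxa x samples count matrix.
#' @return a \linkS4class{SizeFactors}.
#' @export
sizeFactorsPoscounts <- function(counts) {
    n <- ncol(counts)
    logc <- log(counts)
    logc[counts == 0] <- 0
    g <- exp(rowSums(logc) / n)
    s <- vapply(seq_len(n), function(i) {
        y <- counts[, i]
        use <- g > 0 & y > 0
        if (!any(use))
            stop("sample '", colnames(counts)[i],
                 "' shares no positive count with the pseudo-reference")
        median(y[use] / g[use])
    }, numeric(1))
    .newSizeFactors(s, colnames(counts), "poscounts")
}

#' TMM size factors
#'
#' Trimmed mean of M-values: the reference sample is the one whose
#' upper-quartile relative abundance is closest to the mean upper
#' quartile; per sample, log ratios (M) and average log abundances (A)
#' are computed on taxa positive in both the sample and the reference,
#' the extreme \code{trimM} fraction of M and \code{trimA} of A are
#' removed on each side, and the normalization factor is 2^(weighted mean
#' of M) with inverse approximate-variance (delta-method binomial)
#' weights. Factors multiply library sizes to give effective sizes, which
#' are rescaled to geometric-mean-1 size factors.
#'
#' @param counts taxa x samples count matrix (>= 2 samples).
#' @param trimM two-sided trim fraction on M-values (default 0.30).
#' @param trimA two-sided trim fraction on A-values (default 0.05).
#' @return a \linkS4class{SizeFactors}.
#' @export
sizeFactorsTMM <- function(counts, trimM = 0.30, trimA = 0.05) {
    if (ncol(counts) < 2L) stop("TMM needs at least two samples")
    lib <- colSums(counts)
    if (any(lib == 0)) stop("sample with zero library size")
    uq <- apply(counts, 2, function(y) quantile(y, 0.75)) / lib
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(counts)), function(i) {
        .tmmPairFactor(counts[, i], counts[, ref], lib[i], lib[ref],
                       trimM, trimA)
    }, numeric(1))
    eff <- lib * f
    .newSizeFactors(eff, colnames(counts), "tmm")
}

#' @keywords internal
#' @noRd
.tmmPairFactor <- function(obs, ref, nO, nR, trimM, trimA) {
    keep <- obs > 0 & ref > 0
    if (!any(keep))
        stop("sample shares no positive taxa with the TMM reference")
    obs <- obs[keep]; ref <- ref[keep]
    M <- log2((obs / nO) / (ref / nR))
    A <- 0.5 * log2((obs / nO) * (ref / nR))
    v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (length(M) == 0L) return(1)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
        rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

#' GMPR size factors
#'
#' For every ordered sample pair (i, k), r_ik is the median of y_ji /
#' y_jk over taxa positive in both samples; s_i is the geometric mean of
#' r_ik over the samples k sharing support with i, rescaled to geometric
#' mean 1.
#'
#' @param counts taxa x samples count matrix.
#' @return a \linkS4class{SizeFactors}.
#' @export
sizeFactorsGMPR <- function(counts) {
    n <- ncol(counts)
    s <- numeric(n)
    for (i in seq_len(n)) {
        logr <- numeric(0)
        for (k in seq_len(n)) {
            if (k == i) next
            both <- counts[, i] > 0 & counts[, k] > 0
            if (!any(both)) next
            logr <- c(logr, log(median(counts[both, i] / counts[both, k])))
        }
        if (length(logr) == 0L)
            stop("sample '", colnames(counts)[i],
                 "' shares no non-zero taxon with any other sample")
        s[i] <- exp(mean(logr))
    }
    .newSizeFactors(s, colnames(counts), "gmpr")
}

#' log2 counts-per-million
#'
#' log2( (y + prior) / (lib + 2 * prior) * 1e6 ), the standard moderated
#' log-CPM used for MA-style diagnostics.
#'
#' @param counts taxa x samples count matrix with positive library sizes.
#' @param prior pseudo-count (default 0.5).
#' @return matrix of log2 CPM values, same shape as \code{counts}.
#' @export
logCPM <- function(counts, prior = 0.5) {
    lib <- colSums(counts)
    if (any(lib <= 0)) stop("library sizes must be positive")
    t(log2(t(counts + prior) / (lib + 2 * prior) * 1e6))
}
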