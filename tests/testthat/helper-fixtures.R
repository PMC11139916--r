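# Shared fixture builders and independent oracle implementations.
# The oracles are deliberately written as literal transcriptions of the
# size-factor definitions (explicit loops, no code shared with the
# package) so they can serve as an independent cross-check.

toyCounts <- function(nTaxa = 6, nSamples = 4, seed = 1, lambda = 8) {
    set.seed(seed)
    m <- matrix(rpois(nTaxa * nSamples, lambda), nTaxa, nSamples,
                dimnames = list(paste0("t", seq_len(nTaxa)),
                                paste0("s", seq_len(nSamples))))
    storage.mode(m) <- "integer"
    m
}

sparseCounts <- function(nTaxa = 20, nSamples = 6, seed = 1) {
    set.seed(seed)
    m <- matrix(rnbinom(nTaxa * nSamples, mu = 15, size = 1.2),
                nTaxa, nSamples)
    m[matrix(runif(length(m)) < 0.3, nTaxa, nSamples)] <- 0L
    # every sample needs some positive counts for all three schemes
    m[1, ] <- m[1, ] + 5L
    m[2, ] <- m[2, ] + 3L
    storage.mode(m) <- "integer"
    dimnames(m) <- list(paste0("t", seq_len(nTaxa)),
                        paste0("s", seq_len(nSamples)))
    m
}

twoGroupDesign <- function(nPerGroup) {
    n <- 2 * nPerGroup
    X <- cbind(1, rep(c(0, 1), each = nPerGroup))
    colnames(X) <- c("(Intercept)", "grouptreatment")
    X
}

# ---- independent oracles -------------------------------------------------

oraclePoscounts <- function(m) {
    n <- ncol(m)
    g <- numeric(nrow(m))
    for (j in seq_len(nrow(m))) {
        pos <- m[j, ][m[j, ] > 0]
        g[j] <- if (length(pos)) exp(sum(log(pos)) / n) else 0
    }
    s <- numeric(n)
    for (i in seq_len(n)) {
        r <- c()
        for (j in seq_len(nrow(m)))
            if (g[j] > 0 && m[j, i] > 0) r <- c(r, m[j, i] / g[j])
        s[i] <- median(r)
    }
    s / exp(mean(log(s)))
}

oracleGMPR <- function(m) {
    n <- ncol(m)
    s <- numeric(n)
    for (i in seq_len(n)) {
        acc <- c()
        for (k in seq_len(n)) {
            if (k == i) next
            ratios <- c()
            for (j in seq_len(nrow(m)))
                if (m[j, i] > 0 && m[j, k] > 0)
                    ratios <- c(ratios, m[j, i] / m[j, k])
            if (length(ratios)) acc <- c(acc, median(ratios))
        }
        s[i] <- exp(mean(log(acc)))
    }
    s / exp(mean(log(s)))
}

oracleTMM <- function(m, trimM = 0.30, trimA = 0.05) {
    lib <- colSums(m)
    uq <- numeric(ncol(m))
    for (i in seq_len(ncol(m)))
        uq[i] <- quantile(m[, i], 0.75) / lib[i]
    ref <- which.min(abs(uq - mean(uq)))
    f <- numeric(ncol(m))
    for (i in seq_len(ncol(m))) {
        keep <- which(m[, i] > 0 & m[, ref] > 0)
        o <- m[keep, i] / lib[i]
        r <- m[keep, ref] / lib[ref]
        M <- log2(o / r)
        A <- 0.5 * log2(o * r)
        v <- (lib[i] - m[keep, i]) / (lib[i] * m[keep, i]) +
            (lib[ref] - m[keep, ref]) / (lib[ref] * m[keep, ref])
        if (max(abs(M)) < 1e-6) { f[i] <- 1; next }
        nn <- length(M)
        loM <- floor(nn * trimM) + 1; hiM <- nn + 1 - loM
        loA <- floor(nn * trimA) + 1; hiA <- nn + 1 - loA
        sel <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
        f[i] <- 2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
    }
    eff <- lib * f
    eff / exp(mean(log(eff)))
}
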