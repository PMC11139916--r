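test_that("confusion counts match enumeration and a brute-force oracle", {
    c0 <- confusionCounts(rep(FALSE, 5), rep(FALSE, 5))
    expect_equal(unname(c0), c(0L, 0L, 5L, 0L))
    c1 <- confusionCounts(c(TRUE, TRUE, FALSE, FALSE),
                          c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(c1, c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
    set.seed(51)
    for (r in 1:10) {
        truth <- runif(30) < 0.3
        calls <- runif(30) < 0.4
        brute <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
        for (i in 1:30) {
            k <- if (truth[i] && calls[i]) "TP"
                 else if (!truth[i] && calls[i]) "FP"
                 else if (!truth[i] && !calls[i]) "TN" else "FN"
            brute[k] <- brute[k] + 1L
        }
        expect_equal(confusionCounts(truth, calls), brute)
    }
    expect_error(confusionCounts(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("power and FDR follow the stated conventions", {
    m <- daMetrics(c(TP = 8L, FP = 2L, TN = 88L, FN = 2L))
    expect_equal(m$power, 0.8)
    expect_equal(m$fdr, 0.2)
    # no discoveries -> fdr 0; no spiked taxa -> power NaN
    m0 <- daMetrics(c(TP = 0L, FP = 0L, TN = 90L, FN = 10L))
    expect_equal(m0$fdr, 0)
    expect_equal(m0$power, 0)
    mN <- daMetrics(c(TP = 0L, FP = 3L, TN = 97L, FN = 0L))
    expect_true(is.nan(mN$power))
    mP <- daMetrics(c(TP = 10L, FP = 0L, TN = 90L, FN = 0L))
    expect_equal(mP$power, 1); expect_equal(mP$fdr, 0)
})

test_that("type I error is the sub-alpha fraction with NA exclusion", {
    expect_equal(typeOneError(c(0.01, 0.2, 0.6, 0.03)), 0.5)
    expect_equal(typeOneError(rep(1, 10)), 0)
    expect_equal(typeOneError(c(0.01, NA, 0.2)), 0.5)
    expect_true(is.nan(typeOneError(numeric(0))))
    set.seed(52)
    expect_lt(abs(typeOneError(runif(1e4)) - 0.05), 0.01)
})

test_that("benchmark runs are reproducible and structurally complete", {
    tpl <- templatePreset("forest_like")
    b1 <- runBenchmark(tpl, methods = "unweighted", nPerGroup = 8,
                       effects = c(0, 2), nReps = 2, baseSeed = 61)
    b2 <- runBenchmark(tpl, methods = "unweighted", nPerGroup = 8,
                       effects = c(0, 2), nReps = 2, baseSeed = 61)
    expect_identical(b1, b2)
    expect_equal(nrow(b1), 4)
    # null cells report type I error, not power
    expect_true(all(is.nan(b1$power[b1$effect == 0])))
    expect_true(all(is.finite(b1$t1e[b1$effect == 0])))
    expect_true(all(b1$fdr >= 0 & b1$fdr <= 1, na.rm = TRUE))
    s <- benchmarkSummary(b1)
    expect_equal(nrow(s), 2)
})

test_that("unweighted analysis of highly sparse data makes few discoveries at small n and effect", {
    tpl <- templatePreset("forest_like")
    b <- runBenchmark(tpl, methods = "unweighted", nPerGroup = 5,
                      effects = 0.5, nReps = 6, baseSeed = 71)
    expect_lte(median(b$n_sig, na.rm = TRUE), 2)
})
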