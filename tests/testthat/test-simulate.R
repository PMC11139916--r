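test_that("template fitting computes prevalence and floored log-abundance spread", {
    set.seed(41)
    m <- matrix(0L, 2, 10, dimnames = list(c("a", "b"), paste0("s", 1:10)))
    m[1, 1:3] <- c(40L, 60L, 80L)
    m[2, 5] <- 30L
    m <- rbind(m, c = rep(c(100L, 200L), 5))
    tpl <- fitTemplate(m)
    expect_equal(unname(tpl@prevalence[1]), 0.3)
    expect_equal(tpl@sd[2], 0.1)       # single positive -> floor
    expect_equal(tpl@depthLocation, median(colSums(m)))
    mz <- rbind(m, d = rep(0L, 10))
    expect_warning(fitTemplate(mz), "all-zero")
})

test_that("simulated datasets respect the library-size and truth contracts", {
    tpl <- templatePreset("forest_like")
    sp <- makeSpikeDesign(tpl, 1, seed = 3)
    ds <- simulateDataset(tpl, 6, sp, seed = 9)
    m <- counts(ds)
    rd <- SummarizedExperiment::rowData(ds)
    cd <- SummarizedExperiment::colData(ds)
    # truth covers all taxa; spiked flags match the design
    expect_equal(nrow(rd), length(tpl@taxonIds))
    expect_setequal(rownames(ds)[rd$spiked], sp@taxonIds)
    expect_true(all(rd$delta[rd$spiked] != 0))
    # equal group sizes
    expect_equal(as.vector(table(cd$group)), c(6L, 6L))
    # multinomial totals: column sums are the drawn library sizes (>0)
    expect_true(all(colSums(m) >= 1))
    # reproducibility
    ds2 <- simulateDataset(tpl, 6, sp, seed = 9)
    expect_identical(counts(ds2), m)
    expect_identical(as.data.frame(cd), as.data.frame(
        SummarizedExperiment::colData(ds2)))
    ds3 <- simulateDataset(tpl, 6, sp, seed = 10)
    expect_false(identical(counts(ds3), m))
})

test_that("an all-absent template yields an all-zero matrix", {
    tpl <- new("SimTemplate", taxonIds = c("a", "b"),
               prevalence = c(0, 0), m = c(-5, -5), sd = c(0.5, 0.5),
               depthLocation = 1000, depthLogSd = 0.1)
    w <- testthat::capture_warnings(ds <- simulateDataset(tpl, 3, seed = 1))
    expect_true(length(w) >= 1 && all(grepl("no present taxa", w)))
    expect_true(all(counts(ds) == 0))
})

test_that("null simulations have ~exchangeable groups and template-matched zero fraction", {
    tpl <- templatePreset("np_like")
    ds <- simulateDataset(tpl, 25, seed = 5)
    m <- counts(ds)
    g <- SummarizedExperiment::colData(ds)$group
    # zero fraction near the template's expected value
    expect_lt(abs(mean(m == 0) - 0.55), 0.05)
    # rank-sum tests across taxa are calibrated under exchangeability
    set.seed(6)
    taxa <- sample(which(rowSums(m > 0) >= 20), 100)
    pv <- vapply(taxa, function(j)
        suppressWarnings(wilcox.test(m[j, g == "control"],
                                     m[j, g == "treatment"])$p.value),
        numeric(1))
    expect_lt(mean(pv < 0.05, na.rm = TRUE), 0.12)
})

test_that("round trip: data simulated from a fitted template matches its zero fraction", {
    tpl <- templatePreset("forest_like")
    ds <- simulateDataset(tpl, 250, seed = 7)
    fit <- suppressWarnings(fitTemplate(counts(ds)))
    ds2 <- simulateDataset(fit, 250, seed = 8)
    expect_lt(abs(mean(counts(ds2) == 0) - mean(counts(ds) == 0)), 0.05)
})

test_that("spike designs pick prevalent taxa with balanced directions", {
    tpl <- templatePreset("np_like")
    sp <- makeSpikeDesign(tpl, 2, frac = 0.1, seed = 4)
    expect_equal(length(sp@taxonIds), round(0.1 * length(tpl@taxonIds)))
    expect_setequal(unique(abs(sp@delta)), 2)
    expect_lte(abs(sum(sp@delta > 0) - sum(sp@delta < 0)), 1)
    pool <- tpl@taxonIds[tpl@prevalence >=
                         quantile(tpl@prevalence, 0.9)]
    expect_true(all(sp@taxonIds %in% pool))
})

test_that("mock permutations preserve group sizes and are seed-reproducible", {
    groups <- setNames(factor(rep(c("forest", "potting"), c(16, 12))),
                       paste0("s", 1:28))
    mocks <- makeMock(groups, nReps = 20, seed = 2)
    expect_length(mocks, 20)
    for (mk in mocks[1:5])
        expect_equal(as.vector(table(mk)), c(16L, 12L))
    expect_identical(makeMock(groups, nReps = 20, seed = 2), mocks)
    expect_false(identical(makeMock(groups, nReps = 20, seed = 3), mocks))
})
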