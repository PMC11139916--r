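test_that("intercept-only NB fit recovers log(mean) and group symmetry gives zero effect", {
    set.seed(1)
    y <- rpois(30, 9)
    X1 <- matrix(1, 30, 1, dimnames = list(NULL, "(Intercept)"))
    f <- fitNbGlm(y, X1, phi = 0.4, ridge = 0)
    expect_equal(unname(f$beta), log(mean(y)), tolerance = 1e-9)
    # identical group means with equal offsets -> zero group coefficient
    y2 <- rep(c(3L, 5L, 7L), 4)
    X2 <- twoGroupDesign(6)
    f2 <- fitNbGlm(y2, X2, phi = 0.2, ridge = 0)
    expect_lt(abs(f2$beta[2]), 1e-8)
})

test_that("ridge keeps structured-zero fits finite where unpenalized fits diverge", {
    y <- c(0L, 0L, 0L, 5L, 6L, 7L)
    X <- twoGroupDesign(3)
    f0 <- fitNbGlm(y, X, phi = 0.1, ridge = 0)
    f1 <- fitNbGlm(y, X, phi = 0.1, ridge = 1e-6)
    expect_gt(abs(f0$beta[2]), 20)
    expect_lt(abs(f1$beta[2]), 50)
    expect_true(is.finite(f1$loglik))
    # the LRT on the ridge fit is well-defined
    fr <- fitNbGlm(y, X[, 1, drop = FALSE], phi = 0.1, ridge = 1e-6)
    lr <- lrtNb(f1, fr)
    expect_true(is.finite(lr$stat) && lr$pvalue >= 0 && lr$pvalue <= 1)
})

test_that("unit-weight fits equal unweighted fits exactly", {
    set.seed(4)
    y <- rnbinom(24, mu = 12, size = 2)
    X <- twoGroupDesign(12)
    off <- rnorm(24, 0, 0.2)
    fu <- fitNbGlm(y, X, off, NULL, phi = 0.5)
    fw <- fitNbGlm(y, X, off, rep(1, 24), phi = 0.5)
    expect_identical(fu$beta, fw$beta)
    expect_identical(fu$loglik, fw$loglik)
})

test_that("NB fit matches Poisson GLM in the small-dispersion limit", {
    set.seed(5)
    y <- rpois(40, 6)
    X <- twoGroupDesign(20)
    off <- rep(c(0, 0.3), 20)
    f <- fitNbGlm(y, X, off, NULL, phi = 1e-8, ridge = 0)
    g <- glm(y ~ 0 + X, offset = off, family = poisson())
    expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
})

test_that("LRT basics: identity, df, and size-factor rescaling invariance", {
    set.seed(6)
    y <- rnbinom(20, mu = 10, size = 2)
    X <- twoGroupDesign(10)
    f <- fitNbGlm(y, X, phi = 0.5)
    lr0 <- lrtNb(f, f)
    expect_equal(lr0$stat, 0)
    expect_equal(lr0$pvalue, 1)
    expect_error(lrtNb(f, f, 1, 2), "not nested")
    X3 <- cbind(X, extra = rep(c(0, 1), 10))
    f3 <- fitNbGlm(y, X3, phi = 0.5)
    expect_equal(lrtNb(f3, f, 3, 2)$df, 1)
    # multiplying size factors by a constant leaves the LRT unchanged
    m <- matrix(y, 1, dimnames = list("t", paste0("s", 1:20)))
    sf <- exp(rnorm(20, 0, 0.2))
    r1 <- nbTestTaxa(m, X, X[, 1, drop = FALSE], sf)
    r2 <- nbTestTaxa(m, X, X[, 1, drop = FALSE], sf * 2)
    expect_equal(r1$stat, r2$stat, tolerance = 1e-6)
})

test_that("penalized log-likelihood never decreases across accepted IRLS iterates", {
    set.seed(8)
    for (r in 1:5) {
        y <- rnbinom(16, mu = 8, size = 1)
        X <- twoGroupDesign(8)
        f <- fitNbGlm(y, X, phi = 0.7, ridge = 1e-4)
        # refitting from the solution cannot improve it
        f2 <- fitNbGlm(y, X, phi = 0.7, ridge = 1e-4, betaStart = f$beta)
        expect_gte(f2$loglik, f$loglik - 1e-8)
    }
})

test_that("null LRT p-values are uniform", {
    set.seed(11)
    n <- 100
    X <- twoGroupDesign(n / 2)
    m <- matrix(rnbinom(200 * n, mu = 20, size = 2), 200, n,
                dimnames = list(paste0("t", 1:200), paste0("s", 1:n)))
    res <- nbTestTaxa(m, X, X[, 1, drop = FALSE], rep(1, n))
    ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("dispersion estimation recovers truth and hits bounds on degenerate input", {
    set.seed(12)
    X1 <- matrix(1, 500, 1, dimnames = list(NULL, "(Intercept)"))
    y <- rnbinom(500, mu = 50, size = 2)   # phi = 0.5
    phi <- estimateDispersion(matrix(y, 1, dimnames = list("t", NULL)),
                              X1, rep(1, 500))
    expect_gt(phi, 0.4); expect_lt(phi, 0.6)
    # Poisson data: phi at/near the lower bound
    yp <- rpois(200, 30)
    phiP <- estimateDispersion(matrix(yp, 1, dimnames = list("t", NULL)),
                               matrix(1, 200, 1), rep(1, 200))
    expect_lt(phiP, 0.02)
    # identical counts with equal offsets: exactly the lower bound
    yc <- rep(7L, 20)
    phiC <- estimateDispersion(matrix(yc, 1, dimnames = list("t", NULL)),
                               matrix(1, 20, 1), rep(1, 20))
    expect_equal(unname(phiC), 1e-8)
})

test_that("BH adjustment follows the step-up rule and propagates NA", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustBH(0.3), 0.3)
    p <- c(0.01, NA, 0.5, 0.04)
    q <- adjustBH(p)
    expect_true(is.na(q[2]))
    expect_equal(q[-2], p.adjust(p[-2], "BH"))
    # monotone in sorted order
    set.seed(13)
    pr <- runif(50)
    q2 <- adjustBH(pr)
    expect_true(all(diff(q2[order(pr)]) > -1e-12))
    expect_true(all(q2 >= pr - 1e-12))
})
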