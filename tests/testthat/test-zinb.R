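test_that("observation weights follow the posterior-zero formula", {
    # pi = 0.5, f_NB(0) = 0.25 (phi = 1, mu = 3) -> w = 0.125/0.625 = 0.2
    fit <- new("ZinbFit",
               betaMu = matrix(log(3), 1, 1,
                               dimnames = list("t", "(Intercept)")),
               betaPi = matrix(0, 1, 1),
               phi = c(t = 1),
               mu = matrix(3, 1, 2, dimnames = list("t", c("a", "b"))),
               pi = matrix(0.5, 1, 2, dimnames = list("t", c("a", "b"))),
               loglik = 0, converged = TRUE, nIter = 1L)
    m <- matrix(c(0L, 7L), 1, 2, dimnames = list("t", c("a", "b")))
    w <- observationWeights(fit, m)
    expect_equal(unname(w[1, ]), c(0.2, 1))
    # pi ~ 0 gives weight ~ 1 at zeros
    fit@pi[] <- 1e-8
    expect_equal(unname(observationWeights(fit, m)[1, 1]), 1,
                 tolerance = 1e-6)
})

test_that("NB zero probability reaches the Poisson limit as phi -> 0", {
    mu <- c(0.5, 2, 10)
    f0 <- (1 + 1e-8 * mu)^(-1 / 1e-8)
    expect_equal(f0, exp(-mu), tolerance = 1e-6)
})

test_that("taxa without zeros pin pi to the boundary with unit weights", {
    set.seed(21)
    m <- matrix(rpois(40, 30) + 1L, 2, 20,
                dimnames = list(c("a", "b"), paste0("s", 1:20)))
    X <- twoGroupDesign(10)
    rownames(X) <- colnames(m)
    fit <- fitZinb(m, X, rep(1, 20))
    expect_true(all(fit@pi < 1e-6))
    expect_true(all(observationWeights(fit, m) == 1))
})

test_that("the EM does not invent zero inflation on plain NB data", {
    set.seed(22)
    n <- 200
    X <- twoGroupDesign(n / 2)
    m <- matrix(rnbinom(20 * n, mu = 8, size = 1 / 0.6), 20, n,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:n)))
    m[rowSums(m) == 0, 1] <- 1L
    fit <- fitZinb(m, X, rep(1, n))
    expect_lt(mean(fit@pi), 0.05)
})

test_that("the EM recovers known zero-inflation and dispersion at n = 500", {
    set.seed(23)
    n <- 500
    X1 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    m <- t(vapply(1:10, function(j) {
        y <- rnbinom(n, mu = 20, size = 2)      # phi = 0.5
        y[runif(n) < 0.4] <- 0                  # pi = 0.4
        y
    }, numeric(n)))
    storage.mode(m) <- "integer" 
    dimnames(m) <- list(paste0("t", 1:10), paste0("s", 1:n))
    fit <- fitZinb(m, X1, rep(1, n))
    expect_lt(abs(mean(rowMeans(fit@pi)) - 0.4), 0.1)
    expect_lt(abs(median(fit@phi) - 0.5), 0.2)
})

test_that("weights are invariant to relabelling samples with identical data", {
    set.seed(24)
    y <- rnbinom(12, mu = 5, size = 1)
    y[c(2, 7)] <- 0L
    m <- matrix(y, 1, 12, dimnames = list("t", paste0("s", 1:12)))
    X <- twoGroupDesign(6)
    w <- zinbWeights(m, X, rep(1, 12))
    # samples 2 and 7 share covariate pattern within their groups only if
    # the weight model is sample-exchangeable given offset; with unit
    # offsets all zeros in the pooled model get identical weights
    expect_equal(w[1, 2], w[1, 7], tolerance = 1e-8)
})

test_that("downstream weighted fits converge to unweighted fits as pi -> 0", {
    set.seed(25)
    n <- 60
    X <- twoGroupDesign(n / 2)
    m <- matrix(rnbinom(5 * n, mu = 30, size = 2), 5, n,
                dimnames = list(paste0("t", 1:5), paste0("s", 1:n)))
    m[m == 0] <- 1L  # no zeros: weights must all be 1
    w <- zinbWeights(m, X, rep(1, n))
    expect_true(all(w == 1))
    r1 <- nbTestTaxa(m, X, X[, 1, drop = FALSE], rep(1, n), weights = w)
    r0 <- nbTestTaxa(m, X, X[, 1, drop = FALSE], rep(1, n))
    expect_equal(r1$stat, r0$stat, tolerance = 1e-6)
})

test_that("all-zero taxa are rejected and rank deficiency is caught", {
    m <- rbind(a = c(0L, 0L, 0L, 0L), b = c(1L, 2L, 0L, 3L))
    colnames(m) <- paste0("s", 1:4)
    X <- twoGroupDesign(2)
    expect_error(fitZinb(m, X, rep(1, 4)), "all-zero")
    Xbad <- cbind(X, X[, 2])
    expect_error(fitZinb(m[2, , drop = FALSE], Xbad, rep(1, 4)),
                 "rank deficient")
})
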