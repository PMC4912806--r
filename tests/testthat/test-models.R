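test_that("single regression matches hand-computed OLS", {
    f <- fitSingle(c(0, 1, 2), c(0, 1, 1))
    expect_equal(unname(f@coefficients[2]), 0.5)
    expect_equal(f@r.squared, 0.75)
    expect_equal(sum(f@residuals), 0, tolerance = 1e-10)

    # exact collinearity
    fc <- suppressWarnings(fitSingle(1:5, 2 * (1:5) + 1))
    expect_equal(fc@r.squared, 1)

    expect_warning(fy <- fitSingle(c(1, 2, 3), c(4, 4, 4)), "constant")
    expect_equal(fy@r.squared, 0)
    expect_error(fitSingle(c(2, 2, 2), 1:3), "degenerate")
    expect_error(fitSingle(1:2, 1:2), "at least 3")
})

test_that("multiple regression matches the normal-equations oracle", {
    set.seed(21)
    for (rep in 1:6) {
        n <- sample(8:30, 1); p <- sample(1:4, 1)
        X <- matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("f", 1:p)))
        y <- rnorm(n)
        fit <- fitMultiple(X, y)
        expect_equal(unname(fit@coefficients), unname(olsOracle(X, y)),
                     tolerance = 1e-8)
        # row permutation leaves everything unchanged
        ord <- sample(n)
        fitP <- fitMultiple(X[ord, , drop = FALSE], y[ord])
        expect_equal(fit@coefficients, fitP@coefficients)
        expect_equal(fit@sig.factor, fitP@sig.factor)
        expect_equal(fit@r.squared, fitP@r.squared)
    }
})

test_that("rank-deficient designs fail naming the collinear column", {
    X <- cbind(a = rnorm(10), b = 1:10)
    X <- cbind(X, c = X[, "a"] * 2)
    expect_error(fitMultiple(X, rnorm(10)), "collinear.*c")
    expect_error(fitMultiple(matrix(rnorm(6), 3, 2), rnorm(3)),
                 "n > p \\+ 1")
})

test_that("published model forms are refit exactly from noiseless cohorts", {
    for (id in c("eq1", "eq2")) {
        tb <- generateCohortTable(cohortSpec(n = 21, model = id,
                                             noiseSdPct = 0, seed = 5))
        mdl <- publishedModel(id)
        expo <- if (id == "eq1") 1 else 2 / 3
        X <- cbind(v = tb$v_ptv_cm3^expo, hu = tb$hu_mean_shell2mm)
        fit <- suppressWarnings(fitMultiple(X, tb$pct_diff_ptv_d95))
        expect_equal(unname(fit@coefficients),
                     c(mdl@intercept, mdl@coefVolume, mdl@coefHU),
                     tolerance = 1e-9)
        expect_lt(fit@sig.factor, 1e-12)
    }
})

test_that("adding a collinear density feature inflates the P values", {
    tb <- generateCohortTable(cohortSpec(n = 21, noiseSdPct = 2,
                                         seed = 8))
    y <- tb$pct_diff_ptv_d95
    X2 <- cbind(v = tb$v_ptv_cm3^(2 / 3), hu = tb$hu_mean_shell2mm)
    f2 <- fitMultiple(X2, y)
    X3 <- cbind(X2, hu_ptv = tb$hu_mean_ptv)
    f3 <- fitMultiple(X3, y)
    # the shell density loses significance next to its collinear twin
    expect_gt(f3@p.values[["hu"]], f2@p.values[["hu"]])
    expect_gt(f3@sig.factor, f2@sig.factor)
})

test_that("published predictors evaluate the printed coefficient sets", {
    expect_equal(predictPublished(publishedModel("eq2"), 1, 0), 1.16288)
    expect_equal(predictPublished(publishedModel("eq2"), 30.1, -700),
                 23.1, tolerance = 0.005)
    eq1 <- publishedModel("eq1")
    expect_equal(predictPublished(eq1, 1e-9, 0), -0.6623,
                 tolerance = 1e-6)
    expect_equal(predictPublished(eq1, 10, -500),
                 -0.6623 - 0.8136 + 18.92)
    expect_error(publishedModel("eq3"))
    expect_error(predictPublished(eq1, -1, 0), "vPtvCm3")
})

test_that("critical Pearson thresholds reproduce table values", {
    expect_equal(round(criticalPearson(21, 0.01), 2), 0.55)
    expect_equal(criticalPearson(3, 0.05), 0.997, tolerance = 5e-4)
    expect_equal(round(criticalPearson(5, 0.05), 2), 0.88)
    expect_equal(round(criticalPearson(10, 0.05), 2), 0.63)
    expect_equal(round(criticalPearson(30, 0.05), 2), 0.36)
    # strictly decreasing in n at fixed alpha
    rs <- vapply(3:40, criticalPearson, numeric(1), alpha = 0.05)
    expect_true(all(diff(rs) < 0))
    expect_error(criticalPearson(2, 0.05), "n")
    expect_error(criticalPearson(10, 1.2), "alpha")
})

test_that("Mann-Whitney matches exact enumeration on small samples", {
    r <- mannWhitney(c(1, 2), c(3, 4))
    expect_equal(r$U, 0)
    expect_true(r$exact)
    expect_equal(r$p.value, 1 / 3, tolerance = 1e-12)
    expect_equal(r$p.value, enumMannWhitneyP(c(1, 2), c(3, 4)),
                 tolerance = 1e-12)

    set.seed(17)
    for (rep in 1:5) {
        a <- sample(seq(0.1, 30, by = 0.1), sample(2:4, 1))
        b <- sample(setdiff(seq(0.1, 30, by = 0.1), a), sample(2:4, 1))
        r <- mannWhitney(a, b)
        expect_true(r$exact)
        expect_equal(r$p.value, enumMannWhitneyP(a, b),
                     tolerance = 1e-10,
                     info = paste("rep", rep))
    }
})

test_that("Mann-Whitney branches agree and handle ties sensibly", {
    a <- c(1, 2, 3); b <- c(1, 2, 3)
    r <- mannWhitney(a, b)  # ties -> normal approximation
    expect_false(r$exact)
    expect_gt(r$p.value, 0.99)

    set.seed(31)
    x <- rnorm(8); y <- rnorm(8, 0.5)
    rE <- mannWhitney(x, y)
    expect_true(rE$exact)
    rA <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    expect_lt(abs(rE$p.value - rA$p.value), 0.02)
})

test_that("noisy cohorts recover the generating coefficients within 3 SE", {
    mdl <- publishedModel("eq2")
    truth <- c(mdl@intercept, mdl@coefVolume, mdl@coefHU)
    ok <- 0L; nrep <- 200L
    for (s in seq_len(nrep)) {
        tb <- generateCohortTable(cohortSpec(n = 200, noiseSdPct = 2,
                                             seed = 1000 + s))
        X <- cbind(v = tb$v_ptv_cm3^(2 / 3), hu = tb$hu_mean_shell2mm)
        fit <- lm(tb$pct_diff_ptv_d95 ~ X)
        se <- sqrt(diag(vcov(fit)))
        if (all(abs(coef(fit) - truth) <= 3 * se)) ok <- ok + 1L
    }
    expect_gte(ok / nrep, 0.95)
})
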