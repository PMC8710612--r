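test_that("Spearman rho matches rank-Pearson and cor.test", {
    expect_equal(spearmanRho(c(1, 2, 3, 5), c(10, 20, 30, 50))$rho, 1)
    x <- c(1, 2, 3, 4)
    y <- c(2, 1, 4, 3)
    r <- spearmanRho(x, y)
    expect_equal(r$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    set.seed(21)
    for (i in 1:5) {
        a <- rnorm(30)
        b <- 0.4 * a + rnorm(30)
        r <- spearmanRho(a, b)
        ct <- suppressWarnings(cor.test(a, b, method = "spearman",
                                        exact = FALSE))
        expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
        expect_equal(r$p_value, ct$p.value, tolerance = 1e-8)
    }
    expect_equal(spearmanRho(a, -b)$rho, -spearmanRho(a, b)$rho)
    expect_error(spearmanRho(rep(1, 10), rnorm(10)), "zero rank variance")
    expect_error(spearmanRho(1:3, 1:3), "n >= 4")
})

test_that("rho is invariant under strictly monotone transforms", {
    set.seed(8)
    x <- rnorm(40)
    y <- 0.5 * x + rnorm(40)
    base <- spearmanRho(x, y)$rho
    expect_equal(spearmanRho(exp(x), y)$rho, base)
    expect_equal(spearmanRho(x, rank(y) + runif(40, 0, 0.4))$rho, base)
})

test_that("exact permutation p-value agrees with the t approximation", {
    set.seed(31)
    x <- rnorm(7)
    y <- 0.8 * x + rnorm(7, sd = 0.4)
    pe <- spearmanRho(x, y, exact = TRUE)$p_value
    pt_ <- spearmanRho(x, y)$p_value
    expect_lt(abs(pe - pt_), 0.06)
    expect_error(spearmanRho(rnorm(9), rnorm(9), exact = TRUE), "n <= 8")
})

test_that("partial correlation removes a shared confounder", {
    set.seed(15)
    n <- 500
    conf <- cbind(age = runif(n, 62, 81), sex = rep(0:1, n / 2))
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n)
    raw <- spearmanRho(x, y)$rho
    adj <- partialSpearman(x, y, conf)$rho
    expect_lt(abs(adj - raw), 0.05)       # independent confounder: no change
    y2 <- conf[, "age"]
    expect_lt(abs(partialSpearman(x, y2, conf)$rho), 0.05)
    perm <- sample(n)
    expect_equal(partialSpearman(x[perm], y[perm], conf[perm, ])$rho, adj,
                 tolerance = 1e-12)
    expect_error(partialSpearman(x, y, cbind(conf, conf[, 1])), "collinear")
})

test_that("screening flags by unadjusted p and sorts by |rho|", {
    set.seed(23)
    n <- 57
    scores <- round(pmin(80, pmax(20, rnorm(n, 37, 8.6))))
    x <- cbind(strong = -0.8 * scores + rnorm(n, sd = 4),
               weak = rnorm(n),
               noise = rnorm(n))
    out <- screenFeatures(x, scores)
    expect_equal(out$feature[1], "strong")
    expect_true(out$significant[1])
    expect_lt(out$rho[1], 0)
    expect_equal(out$rho, out$rho[order(-abs(out$rho), out$feature)])
    all_f <- screenFeatures(x, scores, alpha = 1)
    expect_true(all(all_f$significant))
})

test_that("null screening flags about alpha of the features", {
    set.seed(29)
    n <- 57
    x <- matrix(rnorm(n * 160), n, 160,
                dimnames = list(NULL, paste0("f", 1:160)))
    out <- screenFeatures(x, sample(20:80, n, replace = TRUE))
    expect_lt(sum(out$significant), 20)
})

test_that("type-I error of the screen is near the nominal level", {
    set.seed(37)
    n <- 57
    reps <- 400
    rej <- vapply(seq_len(reps), function(i)
        spearmanRho(rnorm(n), rnorm(n))$p_value < 0.05, logical(1))
    expect_gt(mean(rej), 0.02)
    expect_lt(mean(rej), 0.09)
})

test_that("post-hoc power follows the Fisher-z formula", {
    expect_equal(posthocPower(0.41, 57),
                 pnorm(sqrt(54) * atanh(0.41) - qnorm(0.975)),
                 tolerance = 1e-12)
    expect_gt(posthocPower(0.41, 57), 0.85)
    expect_lt(posthocPower(0.41, 57), 0.93)
    expect_equal(posthocPower(0, 57), 0.025, tolerance = 1e-6)
    pw <- vapply(c(20, 57, 100, 400), function(n) posthocPower(0.3, n),
                 numeric(1))
    expect_true(all(diff(pw) > 0))
    expect_error(posthocPower(1, 57), "abs")
})
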