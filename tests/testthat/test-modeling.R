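# Tiny deterministic tables for protocol tests.
latentTable <- function(n = 60, p_signal = 4, p_noise = 8, seed = 17,
                        acoustic_names = FALSE) {
    set.seed(seed)
    z <- rnorm(n)
    sig <- sapply(seq_len(p_signal), function(i) 0.8 * z + rnorm(n, sd = 0.6))
    noi <- matrix(rnorm(n * p_noise), n)
    x <- cbind(sig, noi)
    colnames(x) <- if (acoustic_names)
        c(paste0("ac.s", seq_len(p_signal)), paste0("ac.n", seq_len(p_noise)))
    else c(paste0("s", seq_len(p_signal)), paste0("n", seq_len(p_noise)))
    list(x = x, y = round(37 + 8.6 * z), z = z)
}

test_that("cutoff is mean + one sample SD, rounded", {
    set.seed(41)
    v <- rnorm(57)
    scores <- 37 + 8.6 * (v - mean(v)) / sd(v)   # exact mean 37, SD 8.6
    expect_equal(determineCutoff(scores), 46L)
    expect_equal(determineCutoff(rep(30, 5)), 30L)
    expect_equal(determineCutoff(c(20, 40)), 44L)
    labs <- makeClassLabels(c(30, 46, 50), cutoff = 46)
    expect_equal(as.character(labs), c("low", "high", "high"))
})

test_that("classification metrics reproduce printed-cohort arithmetic", {
    m <- classificationMetrics(tp = 9, fn = 1, fp = 1.504, tn = 45.496)
    expect_equal(round(100 * m[["accuracy"]], 1), 95.6)
    expect_equal(round(100 * m[["sensitivity"]], 1), 90.0)
    expect_equal(round(100 * m[["specificity"]], 1), 96.8)
    perfect <- classificationMetrics(10, 0, 0, 47)
    expect_true(all(perfect == 1))
    allneg <- classificationMetrics(0, 10, 0, 47)
    expect_equal(allneg[["accuracy"]], 47 / 57)
    expect_equal(allneg[["sensitivity"]], 0)
    expect_error(classificationMetrics(0, 0, 3, 54), "positive class")
    expect_error(classificationMetrics(3, 2, 0, 0), "negative class")
})

test_that("regression metrics follow their formulas", {
    y <- c(30, 40, 50)
    yhat <- c(32, 38, 56)
    m <- regressionMetrics(y, yhat)
    expect_equal(m[["mae"]], 10 / 3)
    expect_equal(m[["rmse"]], sqrt(44 / 3))
    p <- regressionMetrics(y, y)
    expect_equal(p[["r2"]], 1)
    expect_equal(p[["ev"]], 1)
    expect_equal(regressionMetrics(y, rep(mean(y), 3))[["r2"]], 0)
    expect_error(regressionMetrics(rep(5, 4), 1:4), "constant")
    set.seed(43)
    for (i in 1:10) {
        a <- rnorm(20)
        b <- rnorm(20)
        mm <- regressionMetrics(a, b)
        expect_lte(mm[["mae"]], mm[["rmse"]])
    }
})

test_that("acoustic pre-selection ranks by training-fold correlation", {
    lt <- latentTable(n = 200, p_signal = 16, p_noise = 112, seed = 19,
                      acoustic_names = TRUE)
    sel <- selectAcousticSubset(lt$x, lt$y, k = 16)
    expect_gte(sum(grepl("^ac\\.s", sel)), 12)
    all_sel <- selectAcousticSubset(lt$x, lt$y, k = 1000)
    expect_length(all_sel, ncol(lt$x))
    rho <- abs(apply(lt$x, 2, function(v) cor(rank(v), rank(lt$y))))
    expect_equal(all_sel[1], names(which.max(rho)))
    # disjoint signal carriers in two halves select different subsets
    n <- 100
    set.seed(3)
    z <- rnorm(n)
    xa <- cbind(0.9 * z + rnorm(n, sd = .3), rnorm(n), rnorm(n), rnorm(n))
    xb <- cbind(rnorm(n), rnorm(n), rnorm(n), 0.9 * z + rnorm(n, sd = .3))
    x <- rbind(xa, xb)
    colnames(x) <- paste0("ac.f", 1:4)
    yy <- round(37 + 8.6 * c(z, z))
    expect_false(identical(
        selectAcousticSubset(x[1:n, ], yy[1:n], 1),
        selectAcousticSubset(x[(n + 1):(2 * n), ], yy[(n + 1):(2 * n)], 1)))
})

test_that("SFS first pick equals the brute-force best singleton", {
    lt <- latentTable(n = 60, p_signal = 2, p_noise = 1, seed = 23)
    cands <- colnames(lt$x)
    set.seed(7)
    folds <- sample(rep_len(1:5, 60))
    objs <- vapply(cands, function(cn)
        lonevox:::.innerObjective(lt$x, lt$y, cn, "regression", "knn",
                                  list(k = 5), folds), numeric(1))
    set.seed(7)
    folds2 <- sample(rep_len(1:5, 60))   # same RNG draw as inside SFS
    set.seed(7)
    sel <- sequentialForwardSelection(lt$x, lt$y, cands, "regression",
                                      family = "knn", inner_folds = 5,
                                      max_features = 1)
    expect_equal(sel, names(which.max(objs)))
})

test_that("selected features are unique and drawn from the candidates", {
    lt <- latentTable(n = 60, p_signal = 3, p_noise = 5, seed = 29)
    cands <- colnames(lt$x)[1:6]
    set.seed(11)
    sel <- sequentialForwardSelection(lt$x, lt$y, cands, "regression",
                                      family = "knn", max_features = 5)
    expect_gte(length(sel), 1L)
    expect_false(anyDuplicated(sel) > 0)
    expect_true(all(sel %in% cands))
})

test_that("a perfectly predictive feature is selected first", {
    set.seed(31)
    n <- 200
    x <- cbind(exact = seq_len(n) / n, junk1 = rnorm(n), junk2 = rnorm(n))
    y <- 20 + 60 * x[, "exact"]
    set.seed(5)
    sel <- sequentialForwardSelection(x, y, colnames(x), "regression",
                                      family = "knn", max_features = 3)
    expect_equal(sel[1], "exact")
})

test_that("runCV is deterministic and honest under the null", {
    lt <- latentTable(n = 40, seed = 37)
    set.seed(999)
    y_null <- sample(lt$y)               # break the feature-target link
    r1 <- runCV(lt$x, y_null, task = "regression", family = "knn",
                n_iter = 3, k_folds = 5, seed = 11)
    r2 <- runCV(lt$x, y_null, task = "regression", family = "knn",
                n_iter = 3, k_folds = 5, seed = 11)
    expect_identical(r1@perIteration, r2@perIteration)
    expect_lte(r1@metrics$mean[r1@metrics$metric == "r2"], 0.05)
})

test_that("runCV recovers planted signal and reports bracketing CIs", {
    lt <- latentTable(n = 60, p_signal = 6, p_noise = 6, seed = 41)
    r <- runCV(lt$x, lt$y, task = "regression", family = "knn",
               n_iter = 4, k_folds = 10, seed = 13)
    m <- r@metrics
    expect_gt(m$mean[m$metric == "r2"], 0.3)
    expect_true(all(m$lower <= m$mean & m$mean <= m$upper))
    expect_lte(m$mean[m$metric == "mae"], m$mean[m$metric == "rmse"])
})

test_that("leave-one-out is a valid protocol edge case", {
    lt <- latentTable(n = 12, p_signal = 2, p_noise = 2, seed = 43)
    r <- runCV(lt$x, lt$y, task = "regression", family = "knn",
               n_iter = 1, k_folds = 12, seed = 3, sfs_max_features = 2)
    expect_equal(sum(!is.na(r@predictions[1, ])), 12L)
})

test_that("classification CV is stratified and reports confusion counts", {
    lt <- latentTable(n = 60, p_signal = 6, p_noise = 4, seed = 47)
    labs <- makeClassLabels(lt$y)
    expect_gte(sum(labs == "high"), 5)
    r <- runCV(lt$x, labs, task = "classification", family = "knn",
               n_iter = 2, k_folds = 5, seed = 7)
    expect_equal(sum(r@confusion), 60)
    acc <- classificationMetrics(r@confusion)[["accuracy"]]
    expect_gt(acc, 0.5)
    # one lone positive cannot stratify into both training splits
    y_bad <- factor(c("high", rep("low", 19)), levels = c("low", "high"))
    expect_error(runCV(matrix(rnorm(40), 20,
                              dimnames = list(NULL, c("a", "b"))),
                       y_bad, task = "classification", family = "knn",
                       n_iter = 1, k_folds = 5, seed = 1),
                 "lacks one of the classes")
})

test_that("per-group evaluation matches overall for a single group", {
    lt <- latentTable(n = 40, seed = 53)
    r <- runCV(lt$x, lt$y, task = "regression", family = "knn",
               n_iter = 2, k_folds = 5, seed = 9)
    g1 <- evaluateByGroup(r, rep("all", 40))
    expect_equal(g1$all$mean, r@metrics$mean, tolerance = 1e-12)
    g2 <- evaluateByGroup(r, rep(c("F", "M"), 20))
    expect_length(g2, 2L)
    expect_true(all(is.finite(g2$F$mean)))
    expect_warning(evaluateByGroup(r, c("solo", rep("rest", 39))),
                   "skipped")
})
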