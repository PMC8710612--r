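fakeAcoustics <- function(seed = 1) {
    set.seed(seed)
    setNames(lapply(1:8, function(q)
        setNames(c(500 + q, 1500 + q, runif(14)),
                 c("f1", "f2", paste0("dmfccvar", 1:14)))),
        as.character(1:8))
}
fakeProsody <- function() {
    setNames(lapply(1:8, function(q) c(pitchvar = 20 + q, pause = q / 2)),
             as.character(1:8))
}
fakeLinguistics <- function() {
    fn <- speechFeatureNames()$linguistic
    setNames(seq_along(fn), fn)
}

test_that("canonical names partition 128/16/16 into 160", {
    fn <- speechFeatureNames()
    expect_length(fn$acoustic, 128L)
    expect_length(fn$prosodic, 16L)
    expect_length(fn$linguistic, 16L)
    expect_length(fn$all, 160L)
    expect_false(anyDuplicated(fn$all) > 0)
})

test_that("a complete session assembles to the full named vector", {
    v <- assembleSession(fakeAcoustics(), fakeProsody(), fakeLinguistics())
    expect_length(v, 160L)
    expect_equal(names(v), speechFeatureNames()$all)
    expect_true(all(is.finite(v)))
    expect_equal(v[["ac.f2.q3"]], 1503)
    expect_equal(v[["pr.pause.q4"]], 2)
})

test_that("assembly is keyed by question id, not input order", {
    ac <- fakeAcoustics()
    pr <- fakeProsody()
    li <- fakeLinguistics()
    v1 <- assembleSession(ac, pr, li)
    perm <- as.character(c(5, 3, 8, 1, 2, 7, 6, 4))
    v2 <- assembleSession(ac[perm], pr[perm], li)
    expect_identical(v1, v2)
})

test_that("a missing response is reported by question id", {
    ac <- fakeAcoustics()
    ac[["6"]] <- NULL
    expect_error(assembleSession(ac, fakeProsody(), fakeLinguistics()),
                 "question 6")
})

test_that("failed responses become NA and median imputation fills them", {
    ac <- fakeAcoustics()
    ac[["2"]] <- NULL
    ac <- c(ac, setNames(list(setNames(rep(NA_real_, 16),
                                       c("f1", "f2",
                                         paste0("dmfccvar", 1:14)))), "2"))
    v <- assembleSession(ac, fakeProsody(), fakeLinguistics())
    expect_true(all(is.na(v[paste0(c("ac.f1", "ac.f2"), ".q2")])))
    m <- rbind(v, v, v)
    m[2:3, "ac.f1.q2"] <- c(400, 600)
    filled <- medianImpute(m)
    expect_equal(filled[1, "ac.f1.q2"], 500)
    expect_false(anyNA(filled))
})

test_that("SpeechFeatureSet validates structure and round-trips CSV", {
    fn <- speechFeatureNames()
    set.seed(4)
    feats <- matrix(rnorm(160 * 6), 160, 6, dimnames = list(fn$all, NULL))
    part <- data.frame(participant_id = paste0("p", 1:6),
                       ucla = c(25, 33, 41, 50, 37, 29),
                       age = 62:67, sex = rep(c("F", "M"), 3))
    fs <- speechFeatureSet(feats, part)
    expect_s4_class(fs, "SpeechFeatureSet")
    expect_equal(dim(fs), c(160L, 6L))
    expect_equal(as.integer(table(featureType(fs))[c("acoustic", "prosodic",
                                                     "linguistic")]),
                 c(128L, 16L, 16L))
    expect_equal(uclaScores(fs), part$ucla)
    path <- tempfile(fileext = ".csv")
    writeFeatureTable(fs, path)
    fs2 <- readFeatureTable(path)
    expect_equal(featureMatrix(fs2), featureMatrix(fs), tolerance = 1e-12)
    bad <- part
    bad$ucla[1] <- 90
    expect_error(speechFeatureSet(feats, bad), "20, 80")
})
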