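test_that("cohort spec validates its fields", {
    expect_s3_class(cohortSpec(), "CohortSpec")
    expect_error(cohortSpec(score_bounds = c(10, 80)))
    expect_error(cohortSpec(duration_range = c(12, 4)))
    eff <- lonevox:::.defaultEffects()
    eff$target[1] <- 1.2
    expect_error(cohortSpec(effects = eff))
})

test_that("effect calibration hits the latent Spearman target", {
    spec <- cohortSpec(seed = 2)
    eff <- calibrateEffects(spec, n_pilot = 2000)
    expect_true(all(eff$slope > 0))
    # verify on an independent pilot draw
    set.seed(77)
    z <- rnorm(2000)
    for (i in seq_len(nrow(eff))) {
        L <- eff$slope[i] * z + sqrt(1 - eff$slope[i]^2) * rnorm(2000)
        expect_lt(abs(cor(rank(z), rank(L)) - eff$target[i]), 0.05)
    }
    # zero target gives zero slope; slopes increase with targets
    eff0 <- spec$effects
    eff0$target <- c(0, 0.1, 0.2, 0.3, 0.41, 0.41)
    sp0 <- cohortSpec(effects = eff0, seed = 2)
    cal <- calibrateEffects(sp0, n_pilot = 2000)
    expect_equal(cal$slope[1], 0)
    expect_true(all(diff(cal$slope[1:5]) > 0))
})

test_that("a target of 0.41 lands in the checked band at pilot scale", {
    eff <- lonevox:::.defaultEffects(target = 0.41)
    spec <- cohortSpec(effects = eff, seed = 3)
    cal <- calibrateEffects(spec, n_pilot = 2000)
    set.seed(5)
    z <- rnorm(2000)
    L <- cal$slope[1] * z + sqrt(1 - cal$slope[1]^2) * rnorm(2000)
    rho <- abs(cor(rank(z), rank(L)))
    expect_gt(rho, 0.37)
    expect_lt(rho, 0.45)
})

test_that("sampled cohorts match the study conditions and are reproducible", {
    spec <- cohortSpec(seed = 4)
    cohort <- sampleCohort(spec)
    expect_equal(nrow(cohort), 57L)
    expect_lt(abs(mean(cohort$ucla) - 37), 3)
    expect_lt(abs(sd(cohort$ucla) - 8.6), 3)
    expect_true(all(cohort$ucla >= 20 & cohort$ucla <= 80))
    expect_true(all(cohort$age >= 62 & cohort$age <= 81))
    expect_equal(sort(unique(cohort$sex)), c("F", "M"))
    expect_lte(abs(sum(cohort$sex == "F") - sum(cohort$sex == "M")), 1)
    expect_identical(cohort, sampleCohort(spec))
    expect_true(all(cohort$f2 > 550))
    expect_true(all(cohort$f0_sd > 0))
})

test_that("null effect targets leave the latents uncorrelated", {
    eff <- lonevox:::.defaultEffects(target = 0)
    spec <- cohortSpec(n_participants = 200, effects = eff, seed = 6)
    cohort <- sampleCohort(spec)
    for (v in c("f0_sd", "pause_frac", "f2", "mod_depth", "pos_rate",
                "filler_rate"))
        expect_lt(abs(cor(rank(cohort[[v]]), rank(cohort$ucla))), 0.15)
})

test_that("synthesized responses recover their generating parameters", {
    p <- list(f0_mean = 140, f0_sd = 20, f2 = 1500, mod_depth = 0.3)
    a <- synthesizeResponseAudio(p, question_id = 2, duration_s = 10,
                                 pause_total_s = 2, seed = 21)
    expect_s4_class(a, "AudioResponse")
    expect_equal(duration(a), 10)
    expect_equal(questionId(a), 2L)
    seg <- detectVoiceActivity(a)
    expect_lt(abs(pauseDuration(seg) - 2), 0.3)
    ac <- summarizeResponseAcoustics(a, seg)
    expect_lt(abs(ac[["f2"]] - 1500), 75)
    pr <- summarizeResponseProsody(a, seg)
    expect_lt(abs(pr[["pitchvar"]] - 20), 8)
})

test_that("zero pitch spread collapses extracted pitch variation", {
    p <- list(f0_mean = 140, f0_sd = 0, f2 = 1500, mod_depth = 0.3)
    a <- synthesizeResponseAudio(p, duration_s = 8, pause_total_s = 1.5,
                                 seed = 22)
    pr <- summarizeResponseProsody(a, detectVoiceActivity(a))
    expect_lt(pr[["pitchvar"]], 5)
})

test_that("audio synthesis is seed-deterministic and bounds-checked", {
    p <- list(f0_mean = 140, f0_sd = 15, f2 = 1400, mod_depth = 0.4)
    a1 <- synthesizeResponseAudio(p, duration_s = 5, pause_total_s = 1,
                                  seed = 30)
    a2 <- synthesizeResponseAudio(p, duration_s = 5, pause_total_s = 1,
                                  seed = 30)
    expect_identical(samples(a1), samples(a2))
    a3 <- synthesizeResponseAudio(p, duration_s = 5, pause_total_s = 1,
                                  seed = 31)
    expect_false(identical(samples(a1), samples(a3)))
    expect_error(synthesizeResponseAudio(p, duration_s = 4,
                                         pause_total_s = 3.5, seed = 1),
                 "infeasible")
})

test_that("transcripts follow their category rates", {
    p <- list(pos_rate = 0.1, neg_rate = 0.05, filler_rate = 0.2)
    toks <- synthesizeTranscript(p, 10000, seed = 41)
    expect_length(toks, 10000L)
    expect_lt(abs(fillerProportion(toks, toyFillerWords()) - 0.2), 0.015)
    s <- countSentiment(toks, toyLexicon())
    expect_lt(abs(s[["n_positive"]] / 10000 - 0.1), 0.01)
    expect_equal(synthesizeTranscript(p, 0, seed = 1), character(0))
    p0 <- list(pos_rate = 0, neg_rate = 0.05, filler_rate = 0.2)
    s0 <- countSentiment(synthesizeTranscript(p0, 500, seed = 2),
                         toyLexicon())
    expect_equal(s0[["n_positive"]], 0L)
    expect_error(synthesizeTranscript(list(pos_rate = 0.6, neg_rate = 0.3,
                                           filler_rate = 0.3), 10),
                 "sum")
})

test_that("a session has eight responses and eight transcripts", {
    spec <- cohortSpec(seed = 8)
    cohort <- sampleCohort(spec)
    sess <- generateSession(cohort[1, ], spec, participant_index = 1L)
    expect_length(sess$responses, 8L)
    expect_length(sess$transcripts, 8L)
    durs <- vapply(sess$responses, duration, numeric(1))
    expect_true(all(durs >= spec$duration_range[1] - 1e-6 &
                    durs <= spec$duration_range[2] + 1e-6))
    sess2 <- generateSession(cohort[1, ], spec, participant_index = 1L)
    expect_identical(samples(sess$responses[[3]]),
                     samples(sess2$responses[[3]]))
})

test_that("a written cohort has the full file layout", {
    spec <- cohortSpec(n_participants = 4, seed = 9)
    dir <- tempfile("cohort")
    manifest <- writeCohort(spec, dir)
    expect_equal(nrow(manifest), 32L)
    expect_true(file.exists(file.path(dir, "manifest.csv")))
    expect_true(file.exists(file.path(dir, "participants.csv")))
    expect_true(all(file.exists(file.path(dir, manifest$wav_path))))
    expect_true(all(file.exists(file.path(dir, manifest$transcript_path))))
    # same seed regenerates byte-identical WAVs
    dir2 <- tempfile("cohort")
    writeCohort(spec, dir2)
    f <- manifest$wav_path[1]
    expect_identical(readBin(file.path(dir, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
    unlink(c(dir, dir2), recursive = TRUE)
})
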