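test_that("F0 of pulse trains is recovered within 2 Hz from 80 to 350 Hz", {
    for (f0 in c(80, 120, 200, 283, 350)) {
        a <- pulseTrainAudio(f0)
        tr <- estimateF0Track(a, fullVoiced(a))
        expect_lt(abs(median(tr$f0[tr$voiced]) - f0), 2)
    }
})

test_that("a 100 Hz sine is tracked within 1 Hz", {
    a <- sineAudio(100, 1.5)
    tr <- estimateF0Track(a, fullVoiced(a))
    expect_lt(abs(median(tr$f0[tr$voiced]) - 100), 1)
})

test_that("white-noise frames are flagged unvoiced", {
    set.seed(9)
    a <- audioResponse(rnorm(RATE) * 0.3, RATE)
    tr <- estimateF0Track(a, fullVoiced(a))
    expect_lt(mean(tr$voiced), 0.2)
})

test_that("the lag band must fit in the frame", {
    a <- sineAudio(200, 1)
    expect_error(estimateF0Track(a, fullVoiced(a), f0_min = 10,
                                 frame_s = 0.02),
                 "lag band")
})

test_that("pitch variation is the population SD over voiced frames", {
    tr <- data.frame(f0 = c(100, 200), voiced = c(TRUE, TRUE))
    expect_equal(pitchVariation(tr), 50)
    expect_equal(pitchVariation(data.frame(f0 = rep(150, 6), voiced = TRUE)),
                 0)
    set.seed(2)
    f0 <- rnorm(30, 150, 12)
    base <- pitchVariation(data.frame(f0 = f0, voiced = TRUE))
    shifted <- pitchVariation(data.frame(f0 = f0 + 40, voiced = TRUE))
    expect_equal(base, shifted, tolerance = 1e-12)
    expect_error(pitchVariation(data.frame(f0 = 100, voiced = TRUE)),
                 "voiced frames")
})

test_that("Levinson-Durbin equals the direct normal-equation solve", {
    set.seed(13)
    x <- rnorm(480)
    p <- 12
    r <- vapply(0:p, function(k) sum(x[1:(480 - k)] * x[(k + 1):480]),
                numeric(1))
    a <- levinsonDurbin(r)$a
    direct <- solve(toeplitz(r[1:p]), -r[2:(p + 1)])
    expect_lt(max(abs(a - direct)), 1e-8)
})

test_that("formants of synthesized vowels are recovered", {
    f <- estimateFormants(vowelAudio(500, 1500), fullVoiced(vowelAudio(500, 1500)))
    expect_lt(abs(f[["f1"]] - 500), 50)
    expect_lt(abs(f[["f2"]] - 1500), 75)
    a2 <- vowelAudio(300, 2300)
    f2 <- estimateFormants(a2, fullVoiced(a2))
    expect_lt(abs(f2[["f1"]] - 300) / 300, 0.1)
    expect_lt(abs(f2[["f2"]] - 2300) / 2300, 0.05)
})

test_that("formant recovery error is under 5% in median across the grid", {
    errs <- c()
    for (f1 in seq(300, 800, 125)) {
        for (f2 in seq(900, 2400, 375)) {
            a <- vowelAudio(f1, f2)
            f <- estimateFormants(a, fullVoiced(a))
            errs <- c(errs, abs(f[["f1"]] - f1) / f1,
                      abs(f[["f2"]] - f2) / f2)
        }
    }
    expect_lt(median(errs), 0.05)
})

test_that("formants are amplitude-invariant and fail cleanly on silence", {
    a <- vowelAudio(550, 1600)
    seg <- fullVoiced(a)
    f <- estimateFormants(a, seg)
    a2 <- audioResponse(samples(a) * 2, RATE)
    f2 <- estimateFormants(a2, seg)
    expect_equal(f, f2, tolerance = 1e-6)
    quiet <- audioResponse(numeric(RATE) + 1e-8, RATE)
    expect_error(estimateFormants(quiet, segmentation(0, 1, "silence")),
                 "formants unresolved")
})
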