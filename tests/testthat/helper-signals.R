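# Shared signal builders for the DSP tests.

RATE <- 16000

sineAudio <- function(freq, dur, rate = RATE, amp = 0.5, question_id = 1L) {
    audioResponse(amp * sin(2 * pi * freq * seq_len(round(dur * rate)) / rate),
                  rate, question_id)
}

# silence | tone | silence
gatedSine <- function(freq = 220, dur_sil = 1, dur_tone = 1, rate = RATE) {
    n_sil <- round(dur_sil * rate)
    tone <- 0.5 * sin(2 * pi * freq * seq_len(round(dur_tone * rate)) / rate)
    audioResponse(c(numeric(n_sil), tone, numeric(n_sil)), rate)
}

# pulse train through one or two known resonators (source-filter vowel)
vowelAudio <- function(f1, f2, f0 = 120, dur = 0.6, rate = RATE,
                       bw1 = 80, bw2 = 120) {
    n <- round(dur * rate)
    x <- numeric(n)
    x[seq(1, n, by = round(rate / f0))] <- 1
    for (rf in list(c(f1, bw1), c(f2, bw2))) {
        r <- exp(-pi * rf[2] / rate)
        x <- as.numeric(stats::filter(x, c(2 * r * cos(2 * pi * rf[1] / rate),
                                           -r^2), method = "recursive"))
    }
    audioResponse(x / max(abs(x)) * 0.5, rate)
}

pulseTrainAudio <- function(f0, dur = 2, rate = RATE) {
    n <- round(dur * rate)
    x <- numeric(n)
    t <- 0
    while (t < dur) {
        x[round(t * rate) + 1L] <- 1
        t <- t + 1 / f0
    }
    r <- exp(-pi * 100 / rate)
    y <- stats::filter(x, c(2 * r * cos(2 * pi * 500 / rate), -r^2),
                       method = "recursive")
    audioResponse(as.numeric(y) / max(abs(y)) * 0.5, rate)
}

fullVoiced <- function(audio) segmentation(0, duration(audio), "voice")

# independent MFCC oracle: direct DFT, hand-built triangular filters,
# direct DCT-II summation — no shared code with computeMfcc
oracleMfccFrame <- function(frame, rate, n_mel = 26, n_fft = 512,
                            n_coeff = 14) {
    N <- length(frame)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1) / (N - 1))
    xw <- c(frame * w, numeric(n_fft - N))
    bins <- 0:(n_fft / 2)
    dft <- vapply(bins, function(k)
        abs(sum(xw * exp(-2i * pi * k * (seq_len(n_fft) - 1) / n_fft)))^2,
        numeric(1))
    m2h <- function(m) 700 * (10^(m / 2595) - 1)
    h2m <- function(f) 2595 * log10(1 + f / 700)
    pts <- m2h(seq(0, h2m(rate / 2), length.out = n_mel + 2))
    bin_hz <- bins * rate / n_fft
    E <- vapply(seq_len(n_mel), function(m) {
        wts <- pmax(0, pmin((bin_hz - pts[m]) / (pts[m + 1] - pts[m]),
                            (pts[m + 2] - bin_hz) / (pts[m + 2] - pts[m + 1])))
        sum(wts * dft)
    }, numeric(1))
    logE <- log(pmax(E, 1e-12))
    vapply(seq_len(n_coeff), function(k)
        sum(logE * cos(pi * k * (seq_len(n_mel) - 0.5) / n_mel)),
        numeric(1))
}
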