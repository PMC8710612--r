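# Mel-frequency cepstral coefficients and their first-order deltas.
#
# Chain: Hann-windowed frames of voiced speech -> power spectrum (zero-padded
# FFT) -> triangular mel filterbank energies -> log -> DCT-II, keeping
# coefficients 1..n_coeff (the 0th, pure-loudness coefficient is dropped by
# default). Delta coefficients use the standard regression formula over a
# +/- half_window frame context with replicated edges.

hzToMel <- function(f) 2595 * log10(1 + f / 700)
melToHz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' @param n_mel number of triangular filters.
#' @param n_fft FFT length; the filterbank covers bins \code{0..n_fft/2}.
#' @param rate sampling rate in Hz.
#' @param fmin,fmax frequency range of the bank in Hz.
#' @return matrix \code{n_mel x (n_fft/2 + 1)} of filter weights.
#' @export
melFilterbank <- function(n_mel = 26, n_fft = 512, rate = 16000,
                          fmin = 0, fmax = rate / 2) {
    pts <- melToHz(seq(hzToMel(fmin), hzToMel(fmax), length.out = n_mel + 2))
    bin_hz <- (0:(n_fft / 2)) * rate / n_fft
    fb <- matrix(0, n_mel, n_fft / 2 + 1)
    for (m in seq_len(n_mel)) {
        lo <- pts[m]; ce <- pts[m + 1]; hi <- pts[m + 2]
        up <- (bin_hz - lo) / (ce - lo)
        down <- (hi - bin_hz) / (hi - ce)
        fb[m, ] <- pmax(0, pmin(up, down))
    }
    fb
}

# DCT-II of the rows-are-filters log-energy matrix, coefficients ks;
# plain (unnormalized) transform: C_k = sum_m E_m cos(pi k (m + 0.5) / M).
dctII <- function(loge, ks) {
    M <- nrow(loge)
    basis <- sapply(ks, function(k) cos(pi * k * (seq_len(M) - 0.5) / M))
    t(loge) %*% basis
}

#' MFCCs of the voiced frames of a recording
#'
#' Computes mel-frequency cepstral coefficients for every analysis frame
#' fully contained in a voice segment.
#'
#' @param audio an [AudioResponse-class].
#' @param seg a [Segmentation-class] for the same recording.
#' @param n_coeff number of coefficients to keep (default 14).
#' @param frame_s,hop_s frame length and hop in seconds (default 25/10 ms).
#' @param n_mel number of mel filters (default 26).
#' @param n_fft FFT length (default 512).
#' @param include_c0 if TRUE, keep coefficients \code{0..n_coeff-1} instead
#'   of \code{1..n_coeff} (the default drops the loudness coefficient c0).
#' @return numeric matrix, voiced frames x \code{n_coeff}.
#' @export
computeMfcc <- function(audio, seg, n_coeff = 14, frame_s = 0.025,
                        hop_s = 0.010, n_mel = 26, n_fft = 512,
                        include_c0 = FALSE) {
    stopifnot(is(audio, "AudioResponse"), is(seg, "Segmentation"))
    rate <- audio@rate
    frame_len <- round(frame_s * rate)
    if (frame_len > n_fft)
        stop("frame length exceeds FFT size")
    t0 <- voicedFrameStarts(seg, frame_s, hop_s, duration(audio))
    if (!length(t0)) stop("no voiced speech")
    fr <- frameMatrix(audio@samples, rate, t0, frame_len)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(frame_len) - 1) / (frame_len - 1))
    fr <- fr * w
    padded <- rbind(fr, matrix(0, n_fft - frame_len, ncol(fr)))
    spec <- mvfft(padded)[seq_len(n_fft / 2 + 1), , drop = FALSE]
    power <- Mod(spec)^2
    fb <- melFilterbank(n_mel, n_fft, rate)
    energies <- fb %*% power
    loge <- log(pmax(energies, 1e-12))
    ks <- if (include_c0) 0:(n_coeff - 1) else seq_len(n_coeff)
    cc <- dctII(loge, ks)
    colnames(cc) <- paste0("c", ks)
    cc
}

#' First-order delta coefficients
#'
#' Regression-based temporal derivative of a coefficient track:
#' \deqn{\Delta c_t = \sum_{d=1}^{h} d\,(c_{t+d} - c_{t-d}) / (2 \sum_{d} d^2)}
#' with edge frames replicated.
#'
#' @param mfcc numeric matrix, frames x coefficients.
#' @param half_window regression half-window \eqn{h} in frames (default 2).
#' @return matrix of the same shape as \code{mfcc}.
#' @export
deltaCoefficients <- function(mfcc, half_window = 2) {
    mfcc <- as.matrix(mfcc)
    n <- nrow(mfcc)
    h <- as.integer(half_window)
    if (n < 2L * h + 1L)
        stop("too few frames for the delta window")
    pad <- rbind(mfcc[rep(1L, h), , drop = FALSE], mfcc,
                 mfcc[rep(n, h), , drop = FALSE])
    denom <- 2 * sum((1:h)^2)
    delta <- matrix(0, n, ncol(mfcc), dimnames = dimnames(mfcc))
    for (d in seq_len(h)) {
        idx <- seq_len(n) + h
        delta <- delta + d * (pad[idx + d, , drop = FALSE] -
                              pad[idx - d, , drop = FALSE])
    }
    delta / denom
}

#' Per-coefficient variances of a delta-MFCC track
#'
#' Population variance of each coefficient column across frames; the order
#' follows the coefficient index.
#'
#' @param delta numeric matrix, frames x coefficients.
#' @return named numeric vector of variances (one per coefficient).
#' @export
dmfccVariances <- function(delta) {
    delta <- as.matrix(delta)
    if (nrow(delta) < 2L) stop("need at least 2 frames")
    v <- colMeans(sweep(delta, 2, colMeans(delta))^2)
    names(v) <- colnames(delta)
    v
}
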