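# Formant estimation by linear predictive coding.
#
# Per voiced frame: pre-emphasis, Hamming window, biased autocorrelation,
# Levinson-Durbin recursion for the all-pole coefficients, polynomial roots,
# conversion of upper-half-plane roots to (frequency, bandwidth) pairs, and
# gating to plausible vocal-tract resonances. The response-level F1/F2 is
# the median over frames that yield at least two candidates.

#' Levinson--Durbin recursion
#'
#' Solves the autocorrelation normal equations of linear prediction for the
#' coefficients of \eqn{A(z) = 1 + a_1 z^{-1} + \dots + a_p z^{-p}}.
#'
#' @param r autocorrelation sequence, lags 0..p (length \code{p + 1}).
#' @return list with \code{a} (coefficients \eqn{a_1..a_p}) and \code{err}
#'   (final prediction error power).
#' @export
levinsonDurbin <- function(r) {
    p <- length(r) - 1L
    stopifnot(p >= 1L, r[1L] > 0)
    a <- numeric(0)
    err <- r[1L]
    for (i in seq_len(p)) {
        acc <- r[i + 1L]
        if (i > 1L) acc <- acc + sum(a * r[i:2])
        k <- -acc / err
        a <- if (i == 1L) k else c(a + k * rev(a), k)
        err <- err * (1 - k^2)
        if (err <= 0) break
    }
    list(a = a, err = err)
}

#' First and second formant of a recording
#'
#' @param audio an [AudioResponse-class].
#' @param seg a [Segmentation-class] for the same recording.
#' @param lpc_order all-pole model order; default \code{2 + rate/1000}
#'   (18 at 16 kHz).
#' @param frame_s,hop_s analysis frame length and hop in seconds
#'   (default 30/30 ms, non-overlapping).
#' @param freq_range candidate formant frequency gate in Hz
#'   (default \code{c(90, 4000)}).
#' @param bw_max maximum candidate bandwidth in Hz (default 400).
#' @param preemphasis pre-emphasis coefficient (default 0.5; mild, because a strong pre-emphasis biases low first formants upward when the excitation spectrum is flat).
#' @return named numeric vector \code{c(f1, f2)} in Hz (medians over frames).
#' @export
estimateFormants <- function(audio, seg, lpc_order = NULL, frame_s = 0.030,
                             hop_s = 0.030, freq_range = c(90, 4000),
                             bw_max = 400, preemphasis = 0.5) {
    stopifnot(is(audio, "AudioResponse"), is(seg, "Segmentation"))
    rate <- audio@rate
    if (is.null(lpc_order)) lpc_order <- round(2 + rate / 1000)
    stopifnot(lpc_order >= 4)
    frame_len <- round(frame_s * rate)
    t0 <- voicedFrameStarts(seg, frame_s, hop_s, duration(audio))
    if (!length(t0)) stop("formants unresolved: no voiced frames")
    fr <- frameMatrix(audio@samples, rate, t0, frame_len)
    fr <- fr - rep(colMeans(fr), each = nrow(fr))
    fr <- rbind(fr[1L, , drop = FALSE] * (1 - preemphasis),
                fr[-1L, , drop = FALSE] -
                    preemphasis * fr[-frame_len, , drop = FALSE])
    w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_len) - 1) / (frame_len - 1))
    fr <- fr * w

    # autocorrelation lags 0..p for every frame at once, via FFT
    nfft <- 2^ceiling(log2(frame_len + lpc_order + 1L))
    padded <- rbind(fr, matrix(0, nfft - frame_len, ncol(fr)))
    spec <- mvfft(padded)
    ac <- t(Re(mvfft(Mod(spec)^2, inverse = TRUE))[seq_len(lpc_order + 1L),
                                                   , drop = FALSE]) / nfft
    f1 <- f2 <- rep(NA_real_, ncol(fr))
    for (j in seq_len(ncol(fr))) {
        r <- ac[j, ]
        if (r[1L] <= 0) next
        a <- levinsonDurbin(r)$a
        if (length(a) < lpc_order) next
        roots <- polyroot(rev(c(1, a)))
        roots <- roots[Im(roots) > 0]
        freq <- Arg(roots) * rate / (2 * pi)
        bw <- -rate / pi * log(pmin(Mod(roots), 1 - 1e-12))
        keep <- freq >= freq_range[1L] & freq <= freq_range[2L] & bw < bw_max
        cand <- sort(freq[keep])
        if (length(cand) >= 2L) {
            f1[j] <- cand[1L]
            f2[j] <- cand[2L]
        }
    }
    ok <- is.finite(f1) & is.finite(f2)
    if (!any(ok)) stop("formants unresolved")
    c(f1 = median(f1[ok]), f2 = median(f2[ok]))
}
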