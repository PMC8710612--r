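# Fundamental-frequency estimation by normalized autocorrelation.
#
# Per voiced frame the biased autocorrelation is computed via FFT; the lag
# with the highest normalized autocorrelation inside the period band
# [rate/f0_max, rate/f0_min] gives the period, refined by parabolic
# interpolation around the peak. Frames whose peak falls below the voicing
# threshold are flagged unvoiced.

#' Frame-level fundamental-frequency track
#'
#' @param audio an [AudioResponse-class].
#' @param seg a [Segmentation-class] for the same recording.
#' @param f0_min,f0_max search band in Hz (defaults 60--400).
#' @param frame_s,hop_s frame length and hop in seconds (defaults 40/20 ms;
#'   the frame must hold at least two periods of \code{f0_min}).
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced (default 0.5).
#' @return data.frame with columns \code{time} (frame start, s), \code{f0}
#'   (Hz, NA when unvoiced) and \code{voiced} (logical).
#' @export
estimateF0Track <- function(audio, seg, f0_min = 60, f0_max = 400,
                            frame_s = 0.040, hop_s = 0.020,
                            voicing_threshold = 0.5) {
    stopifnot(is(audio, "AudioResponse"), is(seg, "Segmentation"),
              f0_min < f0_max, f0_min > 0)
    rate <- audio@rate
    frame_len <- round(frame_s * rate)
    lag_lo <- max(2L, floor(rate / f0_max))
    lag_hi <- ceiling(rate / f0_min)
    if (lag_hi + 1L >= frame_len)
        stop("empty lag band: frame too short for f0_min at this rate")
    t0 <- voicedFrameStarts(seg, frame_s, hop_s, duration(audio))
    if (!length(t0))
        return(data.frame(time = numeric(0), f0 = numeric(0),
                          voiced = logical(0)))
    fr <- frameMatrix(audio@samples, rate, t0, frame_len)
    fr <- fr - rep(colMeans(fr), each = nrow(fr))
    nfft <- 2^ceiling(log2(2 * frame_len))
    padded <- rbind(fr, matrix(0, nfft - frame_len, ncol(fr)))
    spec <- mvfft(padded)
    ac <- Re(mvfft(Mod(spec)^2, inverse = TRUE)) / nfft
    r0 <- ac[1L, ]
    r0[r0 <= 0] <- NA
    norm_ac <- ac[seq_len(lag_hi + 2L), , drop = FALSE] /
        rep(r0, each = lag_hi + 2L)

    band <- (lag_lo:lag_hi) + 1L   # +1: row 1 is lag 0
    f0 <- rep(NA_real_, ncol(fr))
    voiced <- rep(FALSE, ncol(fr))
    for (j in seq_len(ncol(fr))) {
        col <- norm_ac[, j]
        if (is.na(r0[j])) next
        k <- band[which.max(col[band])]
        peak <- col[k]
        if (!is.finite(peak) || peak < voicing_threshold) next
        # parabolic refinement of the peak lag
        a <- col[k - 1L]; b <- col[k]; cc <- col[k + 1L]
        denom <- a - 2 * b + cc
        shift <- if (is.finite(denom) && abs(denom) > 1e-12)
            0.5 * (a - cc) / denom else 0
        shift <- max(-0.5, min(0.5, shift))
        lag <- (k - 1L) + shift
        voiced[j] <- TRUE
        f0[j] <- rate / lag
    }
    data.frame(time = t0, f0 = f0, voiced = voiced)
}

#' Pitch variation of an F0 track
#'
#' Population standard deviation of the fundamental frequency over voiced
#' frames — the "inflection" measure: low values indicate monotone speech.
#'
#' @param f0_track data.frame as returned by [estimateF0Track()].
#' @return standard deviation in Hz.
#' @export
pitchVariation <- function(f0_track) {
    f0 <- f0_track$f0[f0_track$voiced]
    f0 <- f0[is.finite(f0)]
    if (length(f0) < 2L) stop("need at least 2 voiced frames")
    sqrt(mean((f0 - mean(f0))^2))
}
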