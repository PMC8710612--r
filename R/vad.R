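# Energy-based voice activity detection.
#
# The recording is tiled into hop-length tiles; each tile's RMS energy is
# measured over an analysis window of length frame_s anchored at the tile
# start (clipped at the signal end). A tile is voice iff its energy in dB
# exceeds the peak tile energy plus energy_floor_db (a negative offset).
# Runs shorter than min_seg_s are merged into the surrounding label.

#' Voice activity detection by frame energy
#'
#' Splits a recording into alternating voice and silence intervals that tile
#' its full duration. A frame is voiced when its RMS energy (dB) exceeds the
#' loudest frame by less than \code{-energy_floor_db}; label runs shorter
#' than \code{min_seg_s} are absorbed into their surroundings, shortest
#' first.
#'
#' @param audio an [AudioResponse-class].
#' @param frame_s analysis window length in seconds (default 0.025).
#' @param energy_floor_db voicing threshold relative to the peak frame RMS,
#'   in dB (negative; default -30).
#' @param min_seg_s minimum segment duration in seconds (default 0.2); must
#'   be >= \code{frame_s}.
#' @param hop_s tile length in seconds (default 0.010).
#' @return A [Segmentation-class] tiling \code{[0, duration(audio)]}.
#' @examples
#' x <- c(rep(0, 8000), sin(2 * pi * 220 * seq_len(8000) / 16000), rep(0, 8000))
#' detectVoiceActivity(audioResponse(x, 16000))
#' @export
detectVoiceActivity <- function(audio, frame_s = 0.025, energy_floor_db = -30,
                                min_seg_s = 0.2, hop_s = 0.010) {
    stopifnot(is(audio, "AudioResponse"), frame_s > 0, hop_s > 0,
              min_seg_s >= frame_s)
    x <- audio@samples
    rate <- audio@rate
    if (length(x) == 0L || all(x == 0)) stop("no signal")
    if (frame_s * rate > length(x))
        stop("frame longer than audio")
    dur <- length(x) / rate
    hop <- max(1L, round(hop_s * rate))
    win <- max(1L, round(frame_s * rate))
    starts <- seq(1L, length(x), by = hop)
    rms <- vapply(starts, function(s) {
        seg <- x[s:min(s + win - 1L, length(x))]
        sqrt(mean(seg^2))
    }, numeric(1))
    db <- 20 * log10(pmax(rms, 1e-12))
    voiced <- db > max(db) + energy_floor_db

    lab <- mergeShortRuns(voiced, min_len = min_seg_s * rate / hop)

    r <- rle(lab)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- c(0L, ends_idx[-length(ends_idx)])
    start_s <- starts_idx * hop / rate
    end_s <- ends_idx * hop / rate
    end_s[length(end_s)] <- dur
    segmentation(start_s, end_s,
                 ifelse(r$values, "voice", "silence"), duration = dur)
}

# Merge runs shorter than min_len frames into the surrounding label,
# shortest first; never merges when only one run remains.
mergeShortRuns <- function(lab, min_len) {
    repeat {
        r <- rle(lab)
        if (length(r$lengths) <= 1L) return(lab)
        short <- which(r$lengths < min_len)
        if (!length(short)) return(lab)
        i <- short[which.min(r$lengths[short])]
        r$values[i] <- !r$values[i]
        lab <- inverse.rle(r)
    }
}

#' Total internal pause duration of a segmentation
#'
#' Sums the durations of silence intervals lying strictly between the first
#' and last voice interval; leading and trailing silence does not count as
#' pausing.
#'
#' @param seg a [Segmentation-class].
#' @return total pause duration in seconds.
#' @export
pauseDuration <- function(seg) {
    stopifnot(is(seg, "Segmentation"))
    v <- which(seg@label == "voice")
    if (!length(v)) stop("no voice interval")
    inner <- which(seg@label == "silence" &
                   seq_along(seg@label) > min(v) &
                   seq_along(seg@label) < max(v))
    if (!length(inner)) return(0)
    sum(seg@end[inner] - seg@start[inner])
}

# Frame start times (seconds) whose [t, t + frame_s) window lies fully
# inside a voice interval. Used by the MFCC, F0 and formant extractors.
voicedFrameStarts <- function(seg, frame_s, hop_s, duration) {
    t0 <- seq(0, duration - frame_s, by = hop_s)
    if (!length(t0)) return(numeric(0))
    keep <- rep(FALSE, length(t0))
    tol <- 1e-9
    for (i in which(seg@label == "voice"))
        keep <- keep | (t0 >= seg@start[i] - tol &
                        t0 + frame_s <= seg@end[i] + tol)
    t0[keep]
}

# Extract a frames-in-columns matrix from samples at the given start times.
frameMatrix <- function(x, rate, start_s, frame_len) {
    idx0 <- round(start_s * rate)
    idx <- outer(seq_len(frame_len), idx0, `+`)
    matrix(x[idx], nrow = frame_len)
}
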