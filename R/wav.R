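# Minimal RIFF WAV reader/writer (PCM 16-bit and IEEE float32), written
# here because no installed package in this stack reads WAV. Stereo input
# is averaged to mono; readWav can resample to the analysis rate.

#' Read a WAV file
#'
#' Supports RIFF PCM 16-bit and IEEE float32, mono or stereo (stereo is
#' averaged to mono). Samples are returned in \eqn{[-1, 1]}; when
#' \code{target_rate} differs from the file rate the signal is resampled
#' with \code{signal::resample}.
#'
#' @param path WAV file path.
#' @param question_id question index stored on the result.
#' @param target_rate desired analysis rate in Hz, or NULL to keep the
#'   file rate.
#' @return an [AudioResponse-class].
#' @export
readWav <- function(path, question_id = 1L, target_rate = 16000) {
    if (!file.exists(path)) stop("no such file: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    riff <- readChar(con, 4, useBytes = TRUE)
    readBin(con, "integer", 1, 4, endian = "little")
    wave <- readChar(con, 4, useBytes = TRUE)
    if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
        stop("not a RIFF/WAVE file: ", path)
    fmt <- NULL
    data <- NULL
    repeat {
        id <- readChar(con, 4, useBytes = TRUE)
        if (length(id) == 0L || nchar(id) < 4L) break
        size <- readBin(con, "integer", 1, 4, endian = "little")
        if (length(size) == 0L) break
        if (id == "fmt ") {
            raw <- readBin(con, "raw", size)
            fmt <- list(
                audio_format = readBin(raw[1:2], "integer", 1, 2,
                                       signed = FALSE, endian = "little"),
                channels = readBin(raw[3:4], "integer", 1, 2,
                                   signed = FALSE, endian = "little"),
                rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
                bits = readBin(raw[15:16], "integer", 1, 2,
                               signed = FALSE, endian = "little"))
        } else if (id == "data") {
            data <- readBin(con, "raw", size)
            break
        } else {
            seek(con, size + size %% 2, origin = "current")
        }
    }
    if (is.null(fmt) || is.null(data))
        stop("malformed WAV (missing fmt or data chunk): ", path)
    x <- if (fmt$audio_format == 1L && fmt$bits == 16L) {
        readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
                endian = "little") / 32768
    } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        readBin(data, "double", length(data) / 4, 4, endian = "little")
    } else stop("unsupported WAV encoding (format ", fmt$audio_format,
                ", ", fmt$bits, " bit)")
    if (fmt$channels > 1L) {
        x <- colMeans(matrix(x, nrow = fmt$channels))
    }
    rate <- fmt$rate
    if (!is.null(target_rate) && target_rate != rate) {
        frac <- .ratioApprox(target_rate / rate)
        x <- as.numeric(signal::resample(x, frac[1], frac[2]))
        rate <- target_rate
    }
    audioResponse(x, rate, question_id)
}

# Small-denominator rational approximation p/q of a resampling ratio.
.ratioApprox <- function(r, max_den = 1000) {
    den <- seq_len(max_den)
    err <- abs(den * r - round(den * r))
    q <- den[which(err < 1e-9)[1]]
    if (is.na(q)) q <- den[which.min(err)]
    c(round(q * r), q)
}

#' Write an AudioResponse as 16-bit PCM WAV
#'
#' @param audio an [AudioResponse-class]; samples are clipped to
#'   \eqn{[-1, 1]}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeWav <- function(audio, path) {
    stopifnot(is(audio, "AudioResponse"))
    x <- pmin(1, pmax(-1, audio@samples))
    pcm <- as.integer(round(x * 32767))
    rate <- as.integer(audio@rate)
    n_bytes <- length(pcm) * 2L
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("RIFF", con, eos = NULL)
    writeBin(36L + n_bytes, con, size = 4, endian = "little")
    writeChar("WAVE", con, eos = NULL)
    writeChar("fmt ", con, eos = NULL)
    writeBin(16L, con, size = 4, endian = "little")
    writeBin(1L, con, size = 2, endian = "little")          # PCM
    writeBin(1L, con, size = 2, endian = "little")          # mono
    writeBin(rate, con, size = 4, endian = "little")
    writeBin(rate * 2L, con, size = 4, endian = "little")   # byte rate
    writeBin(2L, con, size = 2, endian = "little")          # block align
    writeBin(16L, con, size = 2, endian = "little")         # bits
    writeChar("data", con, eos = NULL)
    writeBin(n_bytes, con, size = 4, endian = "little")
    writeBin(pcm, con, size = 2, endian = "little")
    invisible(path)
}
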