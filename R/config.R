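# Analysis configuration: one flat, serializable list of every tunable
# numeric choice in the extraction chain, validated on construction so a
# pipeline run can be reproduced from its config echo alone.

.configDefaults <- function() list(
    rate = 16000,
    vad_frame_s = 0.025, vad_hop_s = 0.010,
    vad_floor_db = -30, vad_min_seg_s = 0.2,
    mfcc_n_coeff = 14, mfcc_frame_s = 0.025, mfcc_hop_s = 0.010,
    mfcc_n_mel = 26, mfcc_n_fft = 512, mfcc_include_c0 = FALSE,
    delta_half_window = 2,
    f0_min = 60, f0_max = 400, f0_frame_s = 0.040, f0_hop_s = 0.020,
    f0_voicing_threshold = 0.5,
    formant_lpc_order = NA, formant_frame_s = 0.030, formant_hop_s = 0.030,
    formant_freq_min = 90, formant_freq_max = 4000, formant_bw_max = 400,
    formant_preemphasis = 0.5,
    sentiment_questions = c(3L, 6L, 7L, 8L),
    sfs_max_features = 12, sfs_inner_folds = 5,
    cv_iterations = 20, cv_folds = 10,
    seed = 1L
)

#' Analysis configuration
#'
#' Returns the full set of extraction and evaluation parameters as a flat
#' named list. Any subset can be overridden by name; unknown names are
#' rejected. Durations are in seconds, frequencies in Hz.
#'
#' @param ... named overrides of the defaults (see
#'   \code{lonevox:::.configDefaults()} for the complete set: VAD frame/hop
#'   and threshold, MFCC filterbank and coefficient choices, delta window,
#'   F0 band and voicing threshold, LPC/formant gates, the four
#'   sentiment-scored questions, SFS and cross-validation sizes, seed).
#' @return named list of class \code{"SpeechConfig"}.
#' @examples
#' cfg <- speechConfig(vad_floor_db = -35)
#' @export
speechConfig <- function(...) {
    cfg <- .configDefaults()
    ov <- list(...)
    if (length(ov)) {
        if (is.null(names(ov)) || any(names(ov) == ""))
            stop("all config overrides must be named")
        unknown <- setdiff(names(ov), names(cfg))
        if (length(unknown))
            stop("unknown config fields: ", paste(unknown, collapse = ", "))
        cfg[names(ov)] <- ov
    }
    with(cfg, {
        stopifnot(rate > 0, vad_frame_s > 0, vad_hop_s > 0,
                  vad_min_seg_s >= vad_frame_s, vad_floor_db < 0,
                  mfcc_n_coeff >= 1, mfcc_n_fft >= mfcc_frame_s * rate,
                  delta_half_window >= 1, f0_min > 0, f0_min < f0_max,
                  formant_freq_min < formant_freq_max, formant_bw_max > 0,
                  length(sentiment_questions) == 4,
                  all(sentiment_questions %in% 1:8),
                  sfs_max_features >= 1, sfs_inner_folds >= 2,
                  cv_iterations >= 1, cv_folds >= 2)
    })
    structure(cfg, class = "SpeechConfig")
}

#' Write / read a configuration as JSON
#'
#' @param config a \code{SpeechConfig} list from [speechConfig()].
#' @param path file path for the JSON document.
#' @return \code{readSpeechConfig} returns a validated \code{SpeechConfig}.
#' @export
writeSpeechConfig <- function(config, path) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeSpeechConfig
#' @export
readSpeechConfig <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(speechConfig, raw)
}

# Deterministic per-stage seed derivation from the root seed: a small fixed
# offset per stage name keeps every derived seed below 2^31.
deriveSeed <- function(seed, stage, k = 0L) {
    offsets <- c(cohort = 11L, audio = 23L, transcript = 37L, cv = 51L,
                 screen = 67L, calibrate = 83L)
    stopifnot(stage %in% names(offsets))
    (as.integer(seed) + offsets[[stage]] * 1009L + as.integer(k) * 7L) %%
        2147483647L
}
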