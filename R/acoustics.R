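#' Acoustic summary of one question response
#'
#' Composes the MFCC chain (MFCC frames of voiced speech, first-order
#' deltas, per-coefficient variances) and LPC formant estimation into the
#' 16 acoustic values a single response contributes: F1, F2 and the 14
#' delta-MFCC variances.
#'
#' @param audio an [AudioResponse-class].
#' @param seg a [Segmentation-class]; computed with [detectVoiceActivity()]
#'   defaults when omitted.
#' @param config a \code{SpeechConfig} from [speechConfig()].
#' @return named numeric vector of length 16:
#'   \code{f1}, \code{f2}, \code{dmfccvar1} .. \code{dmfccvar14}.
#' @export
summarizeResponseAcoustics <- function(audio, seg = NULL,
                                       config = speechConfig()) {
    if (is.null(seg))
        seg <- detectVoiceActivity(audio, config$vad_frame_s,
                                   config$vad_floor_db, config$vad_min_seg_s,
                                   config$vad_hop_s)
    cc <- computeMfcc(audio, seg, n_coeff = config$mfcc_n_coeff,
                      frame_s = config$mfcc_frame_s, hop_s = config$mfcc_hop_s,
                      n_mel = config$mfcc_n_mel, n_fft = config$mfcc_n_fft,
                      include_c0 = config$mfcc_include_c0)
    dv <- dmfccVariances(deltaCoefficients(cc, config$delta_half_window))
    lpc_order <- if (is.na(config$formant_lpc_order)) NULL else
        config$formant_lpc_order
    ff <- estimateFormants(audio, seg, lpc_order = lpc_order,
                           frame_s = config$formant_frame_s,
                           hop_s = config$formant_hop_s,
                           freq_range = c(config$formant_freq_min,
                                          config$formant_freq_max),
                           bw_max = config$formant_bw_max,
                           preemphasis = config$formant_preemphasis)
    out <- c(ff, dv)
    names(out) <- c("f1", "f2", paste0("dmfccvar", seq_len(config$mfcc_n_coeff)))
    out
}

#' Prosodic summary of one question response
#'
#' @inheritParams summarizeResponseAcoustics
#' @return named numeric vector \code{c(pitchvar, pause)}: population SD of
#'   frame F0 over voiced frames (Hz) and total internal pause duration (s).
#' @export
summarizeResponseProsody <- function(audio, seg = NULL,
                                     config = speechConfig()) {
    if (is.null(seg))
        seg <- detectVoiceActivity(audio, config$vad_frame_s,
                                   config$vad_floor_db, config$vad_min_seg_s,
                                   config$vad_hop_s)
    track <- estimateF0Track(audio, seg, f0_min = config$f0_min,
                             f0_max = config$f0_max,
                             frame_s = config$f0_frame_s,
                             hop_s = config$f0_hop_s,
                             voicing_threshold = config$f0_voicing_threshold)
    c(pitchvar = pitchVariation(track), pause = pauseDuration(seg))
}
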