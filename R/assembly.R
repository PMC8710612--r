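# The fixed 160-dimensional session feature vector: 128 acoustic
# ((F1, F2, 14 delta-MFCC variances) x 8 questions), 16 prosodic
# ((pitch variation, pause duration) x 8) and 16 linguistic
# (positive + negative counts on 4 questions, filler proportion on 8).

#' Canonical speech feature names
#'
#' @param n_coeff number of delta-MFCC variance features per question
#'   (default 14).
#' @param sentiment_questions the four sentiment-scored question ids.
#' @return list with components \code{acoustic} (128), \code{prosodic}
#'   (16), \code{linguistic} (16) and \code{all} (160), in canonical order.
#' @export
speechFeatureNames <- function(n_coeff = 14,
                               sentiment_questions = c(3L, 6L, 7L, 8L)) {
    ac <- unlist(lapply(1:8, function(q)
        paste0(c("ac.f1", "ac.f2", paste0("ac.dmfccvar", seq_len(n_coeff))),
               ".q", q)))
    pr <- c(paste0("pr.pitchvar.q", 1:8), paste0("pr.pause.q", 1:8))
    sq <- sort(as.integer(sentiment_questions))
    li <- c(unlist(lapply(sq, function(q)
        paste0(c("li.pos", "li.neg"), ".q", q))),
        paste0("li.filler.q", 1:8))
    list(acoustic = ac, prosodic = pr, linguistic = li,
         all = c(ac, pr, li))
}

#' Assemble one session feature vector
#'
#' Combines per-question acoustic and prosodic summaries with the session
#' linguistic block into the named 160-dimensional vector. Inputs are keyed
#' by question id, so input order is irrelevant.
#'
#' @param acoustics named list (\code{"1"}..\code{"8"}) of 16-value vectors
#'   from [summarizeResponseAcoustics()]; an entry may be NULL or contain
#'   NA when a response failed extraction — the corresponding features are
#'   recorded as NA and imputed downstream.
#' @param prosody named list (\code{"1"}..\code{"8"}) of 2-value vectors
#'   from [summarizeResponseProsody()].
#' @param linguistics 16-value named vector from
#'   [summarizeSessionLinguistics()].
#' @param sentiment_questions the four sentiment question ids.
#' @return named numeric vector of length 160, partition 128/16/16.
#' @export
assembleSession <- function(acoustics, prosody, linguistics,
                            sentiment_questions = c(3L, 6L, 7L, 8L)) {
    fn <- speechFeatureNames(sentiment_questions = sentiment_questions)
    if (is.null(names(acoustics)) && length(acoustics) == 8L)
        names(acoustics) <- as.character(1:8)
    if (is.null(names(prosody)) && length(prosody) == 8L)
        names(prosody) <- as.character(1:8)
    for (q in as.character(1:8)) {
        if (!q %in% names(acoustics))
            stop("missing acoustic summary for question ", q)
        if (!q %in% names(prosody))
            stop("missing prosodic summary for question ", q)
    }
    out <- setNames(rep(NA_real_, length(fn$all)), fn$all)
    for (q in 1:8) {
        a <- acoustics[[as.character(q)]]
        if (!is.null(a))
            out[paste0("ac.", sub("^ac\\.", "", names(a)), ".q", q)] <-
                as.numeric(a)
        p <- prosody[[as.character(q)]]
        if (!is.null(p))
            out[paste0("pr.", names(p), ".q", q)] <- as.numeric(p)
    }
    if (length(linguistics) != 16L || is.null(names(linguistics)))
        stop("linguistics must be the 16 named session features")
    out[names(linguistics)] <- as.numeric(linguistics)
    out
}

#' Extract the full feature vector of one session
#'
#' Runs VAD, the acoustic/prosodic extractors and the linguistic counters
#' on eight (recording, transcript) pairs. A response whose acoustic or
#' prosodic extraction fails (e.g. unresolved formants) contributes NA for
#' the affected features; NAs are later imputed with training-set medians
#' at modeling time.
#'
#' @param responses list of 8 [AudioResponse-class] objects (question order
#'   or named \code{"1"}..\code{"8"}).
#' @param transcripts list of 8 token vectors (or strings, tokenized with
#'   the default tokenizer).
#' @param lexicon,filler_set sentiment lexicon and filler list (defaults:
#'   the bundled toy dictionaries).
#' @param config a \code{SpeechConfig}.
#' @return named numeric vector of length 160.
#' @export
extractSessionFeatures <- function(responses, transcripts,
                                   lexicon = toyLexicon(),
                                   filler_set = toyFillerWords(),
                                   config = speechConfig()) {
    stopifnot(length(responses) == 8L, length(transcripts) == 8L)
    if (is.null(names(responses))) names(responses) <- as.character(1:8)
    if (is.null(names(transcripts))) names(transcripts) <- as.character(1:8)
    acoustics <- prosody <- setNames(vector("list", 8L), as.character(1:8))
    for (q in as.character(1:8)) {
        audio <- responses[[q]]
        seg <- tryCatch(
            detectVoiceActivity(audio, config$vad_frame_s,
                                config$vad_floor_db, config$vad_min_seg_s,
                                config$vad_hop_s),
            error = function(e) NULL)
        if (is.null(seg)) next
        acoustics[[q]] <- tryCatch(
            summarizeResponseAcoustics(audio, seg, config),
            error = function(e) NULL)
        prosody[[q]] <- tryCatch(
            summarizeResponseProsody(audio, seg, config),
            error = function(e) NULL)
    }
    toks <- lapply(transcripts, function(tr)
        if (is.character(tr) && length(tr) == 1L) tokenizeTranscript(tr)
        else as.character(tr))
    li <- summarizeSessionLinguistics(toks, lexicon, filler_set,
                                      config$sentiment_questions)
    # NULL prosody/acoustics entries must still key the assembly
    for (q in as.character(1:8)) {
        if (is.null(acoustics[[q]]))
            acoustics[[q]] <- setNames(rep(NA_real_, 16),
                                       c("f1", "f2",
                                         paste0("dmfccvar", 1:14)))
        if (is.null(prosody[[q]]))
            prosody[[q]] <- c(pitchvar = NA_real_, pause = NA_real_)
    }
    assembleSession(acoustics, prosody, li,
                    sentiment_questions = config$sentiment_questions)
}

#' Median-impute missing feature values
#'
#' @param x numeric matrix (participants x features).
#' @param medians optional named medians (e.g. from a training fold); when
#'   NULL the column medians of \code{x} are used.
#' @return matrix with NAs replaced; columns that are entirely NA become 0.
#' @export
medianImpute <- function(x, medians = NULL) {
    x <- as.matrix(x)
    if (is.null(medians))
        medians <- apply(x, 2, median, na.rm = TRUE)
    medians[!is.finite(medians)] <- 0
    for (j in seq_len(ncol(x))) {
        nas <- is.na(x[, j])
        if (any(nas)) x[nas, j] <- medians[[j]]
    }
    x
}

#' Write / read a cohort feature table as CSV
#'
#' One row per participant: \code{participant_id, ucla, age, sex} followed
#' by the 160 feature columns in canonical order.
#'
#' @param fs a [SpeechFeatureSet-class].
#' @param path CSV file path.
#' @return \code{readFeatureTable} returns a [SpeechFeatureSet-class].
#' @export
writeFeatureTable <- function(fs, path) {
    stopifnot(is(fs, "SpeechFeatureSet"))
    cd <- as.data.frame(SummarizedExperiment::colData(fs))
    if (!"participant_id" %in% colnames(cd))
        cd <- cbind(participant_id = colnames(fs), cd)
    tab <- cbind(cd[c("participant_id", "ucla", "age", "sex")],
                 as.data.frame(featureMatrix(fs), check.names = FALSE))
    write.csv(tab, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    tab <- read.csv(path, check.names = FALSE)
    fn <- speechFeatureNames()
    miss <- setdiff(fn$all, colnames(tab))
    if (length(miss))
        stop("feature table lacks columns: ", paste(head(miss, 5),
                                                    collapse = ", "))
    feat <- t(as.matrix(tab[, fn$all, drop = FALSE]))
    colnames(feat) <- as.character(tab$participant_id)
    speechFeatureSet(feat, tab[, c("participant_id", "ucla", "age", "sex")])
}
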