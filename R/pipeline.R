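# File-based pipeline: manifest + participants table in, feature table,
# screening report and evaluation reports out.

#' Read and validate a session manifest
#'
#' @param path CSV with columns \code{participant_id}, \code{question_id},
#'   \code{wav_path}, \code{transcript_path}; every participant must have
#'   exactly 8 rows, one per question.
#' @return the manifest data.frame.
#' @export
readManifest <- function(path) {
    m <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("participant_id", "question_id", "wav_path", "transcript_path")
    miss <- setdiff(need, colnames(m))
    if (length(miss)) stop("manifest lacks columns: ",
                           paste(miss, collapse = ", "))
    for (pid in unique(m$participant_id)) {
        qs <- sort(m$question_id[m$participant_id == pid])
        if (!identical(as.integer(qs), 1:8))
            stop("participant ", pid, " is missing question ",
                 setdiff(1:8, qs)[1])
    }
    m
}

#' Extract cohort features from files
#'
#' Reads every WAV and transcript referenced by the manifest, extracts the
#' 160 session features per participant and returns the cohort container.
#'
#' @param manifest manifest data.frame (see [readManifest()]) or a path.
#' @param participants data.frame with \code{participant_id},
#'   \code{ucla}, \code{age}, \code{sex}, or a CSV path.
#' @param dir directory that relative wav/transcript paths resolve
#'   against.
#' @param lexicon,filler_set dictionaries (defaults: bundled toy files).
#' @param config a \code{SpeechConfig}.
#' @return a [SpeechFeatureSet-class].
#' @export
extractCohortFeatures <- function(manifest, participants, dir = ".",
                                  lexicon = toyLexicon(),
                                  filler_set = toyFillerWords(),
                                  config = speechConfig()) {
    if (is.character(manifest)) manifest <- readManifest(manifest)
    if (is.character(participants))
        participants <- read.csv(participants, stringsAsFactors = FALSE)
    pids <- unique(manifest$participant_id)
    if (!all(pids %in% participants$participant_id))
        stop("manifest participant missing from participants table")
    participants <- participants[match(pids, participants$participant_id), ]
    fn <- speechFeatureNames()
    feats <- matrix(NA_real_, length(fn$all), length(pids),
                    dimnames = list(fn$all, pids))
    resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
    for (i in seq_along(pids)) {
        rows <- manifest[manifest$participant_id == pids[i], ]
        rows <- rows[order(rows$question_id), ]
        responses <- transcripts <- setNames(vector("list", 8L),
                                             as.character(1:8))
        for (q in 1:8) {
            r <- rows[rows$question_id == q, ]
            responses[[q]] <- readWav(resolve(r$wav_path), q,
                                      target_rate = config$rate)
            transcripts[[q]] <- paste(readLines(resolve(r$transcript_path),
                                                warn = FALSE),
                                      collapse = " ")
        }
        feats[, i] <- extractSessionFeatures(responses, transcripts,
                                             lexicon, filler_set, config)
    }
    speechFeatureSet(feats,
                     participants[, c("participant_id", "ucla", "age",
                                      "sex")])
}

#' Run the full analysis pipeline
#'
#' Extract (or accept) the cohort features, screen every feature against
#' the UCLA score, derive the high-loneliness cutoff, and evaluate
#' regression and classification models for the requested feature input
#' sets (P = prosodic, A = acoustic, L = linguistic, PAL = all three).
#'
#' @param features a [SpeechFeatureSet-class] (e.g. from
#'   [buildCohortFeatureSet()] or [extractCohortFeatures()]).
#' @param tasks subset of \code{c("regression", "classification")}.
#' @param input_sets subset of \code{c("P", "A", "L", "PAL")}.
#' @param family model family for [runCV()].
#' @param n_iter,k_folds cross-validation protocol sizes.
#' @param seed root seed.
#' @param out_dir if non-NULL, write \code{features.csv},
#'   \code{screening.csv}, \code{report.json} and a config echo there.
#' @param config a \code{SpeechConfig} (echoed to \code{out_dir}).
#' @param ... further arguments to [runCV()].
#' @return list with \code{screening} (data.frame), \code{cutoff}
#'   (integer), \code{labels} (factor) and \code{reports} (nested list
#'   \code{reports[[task]][[input_set]]} of [EvalReport-class]).
#' @export
runPipeline <- function(features, tasks = c("regression", "classification"),
                        input_sets = c("P", "A", "L", "PAL"),
                        family = "svm", n_iter = 20, k_folds = 10,
                        seed = 1, out_dir = NULL,
                        config = speechConfig(), ...) {
    stopifnot(is(features, "SpeechFeatureSet"))
    scores <- uclaScores(features)
    screening <- screenFeatures(features, adjust = TRUE)
    cutoff <- determineCutoff(scores)
    labels <- makeClassLabels(scores, cutoff)
    fn <- speechFeatureNames()
    cols <- list(P = fn$prosodic, A = fn$acoustic, L = fn$linguistic,
                 PAL = fn$all)
    x <- featureMatrix(features)
    reports <- list()
    for (task in tasks) {
        reports[[task]] <- list()
        for (s in input_sets) {
            targets <- if (task == "regression") scores else labels
            reports[[task]][[s]] <- runCV(
                x[, cols[[s]], drop = FALSE], targets, task = task,
                family = family, n_iter = n_iter, k_folds = k_folds,
                seed = seed, preselect_scores = scores, ...)
        }
    }
    out <- list(screening = screening, cutoff = cutoff, labels = labels,
                reports = reports)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeFeatureTable(features, file.path(out_dir, "features.csv"))
        write.csv(screening, file.path(out_dir, "screening.csv"),
                  row.names = FALSE)
        writeSpeechConfig(config, file.path(out_dir, "config.json"))
        json <- list(cutoff = cutoff,
                     n_high = sum(labels == "high"),
                     reports = lapply(reports, function(tl)
                         lapply(tl, function(r) list(
                             family = r@family,
                             metrics = r@metrics,
                             confusion = as.list(r@confusion)))))
        jsonlite::write_json(json, file.path(out_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
    }
    out
}
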