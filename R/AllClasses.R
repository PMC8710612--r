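#' @import methods
#' @importFrom stats cor fft lm.fit median mvfft pnorm predict pt qnorm qt
#'   plogis qlogis rnorm runif sd setNames var
#' @importFrom utils head read.csv read.delim write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Single-question speech recording
#'
#' Holds one mono speech recording: real-valued samples in \eqn{[-1, 1]}
#' together with the sampling rate and the index (1--8) of the daily-life
#' question it answers.
#'
#' @slot samples numeric vector of amplitudes in \eqn{[-1, 1]}.
#' @slot rate sampling rate in Hz.
#' @slot questionId integer question index, 1--8.
#'
#' @seealso [audioResponse()], [detectVoiceActivity()]
#' @exportClass AudioResponse
setClass("AudioResponse",
         representation(samples = "numeric", rate = "numeric",
                        questionId = "integer"))

setValidity("AudioResponse", function(object) {
    msg <- character()
    if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
        msg <- c(msg, "'rate' must be a single positive number")
    if (length(object@samples) < 1L)
        msg <- c(msg, "'samples' must be non-empty")
    if (anyNA(object@samples))
        msg <- c(msg, "'samples' must not contain NA")
    if (length(object@questionId) != 1L || is.na(object@questionId) ||
        object@questionId < 1L || object@questionId > 8L)
        msg <- c(msg, "'questionId' must be an integer in 1..8")
    if (length(msg)) msg else TRUE
})

#' Construct an AudioResponse
#'
#' @param samples numeric amplitude vector; values outside \eqn{[-1, 1]} are
#'   accepted but unusual for normalized audio.
#' @param rate sampling rate in Hz.
#' @param question_id question index in 1--8 (default 1).
#' @return An [AudioResponse-class] object.
#' @examples
#' a <- audioResponse(sin(2 * pi * 220 * seq(0, 1, by = 1/16000)), 16000)
#' duration(a)
#' @export
audioResponse <- function(samples, rate, question_id = 1L) {
    new("AudioResponse", samples = as.numeric(samples), rate = as.numeric(rate),
        questionId = as.integer(question_id))
}

#' Voice/silence segmentation of a recording
#'
#' An ordered set of intervals labelled \code{"voice"} or \code{"silence"}
#' that tiles \eqn{[0, duration]} exactly, with alternating labels.
#'
#' @slot start,end numeric vectors of interval bounds in seconds.
#' @slot label character vector, each \code{"voice"} or \code{"silence"}.
#' @slot duration total duration in seconds.
#'
#' @seealso [detectVoiceActivity()], [pauseDuration()]
#' @exportClass Segmentation
setClass("Segmentation",
         representation(start = "numeric", end = "numeric",
                        label = "character", duration = "numeric"))

setValidity("Segmentation", function(object) {
    msg <- character()
    n <- length(object@start)
    if (length(object@end) != n || length(object@label) != n)
        msg <- c(msg, "start, end and label must have equal length")
    if (n == 0L)
        msg <- c(msg, "segmentation must contain at least one interval")
    if (!all(object@label %in% c("voice", "silence")))
        msg <- c(msg, "labels must be 'voice' or 'silence'")
    if (n > 0L) {
        if (any(object@end <= object@start))
            msg <- c(msg, "every interval needs start < end")
        tol <- 1e-9
        if (abs(object@start[1L]) > tol)
            msg <- c(msg, "first interval must start at 0")
        if (abs(object@end[n] - object@duration) > 1e-6)
            msg <- c(msg, "last interval must end at the total duration")
        if (n > 1L) {
            if (any(abs(object@start[-1L] - object@end[-n]) > tol))
                msg <- c(msg, "intervals must tile without gap or overlap")
            if (any(object@label[-1L] == object@label[-n]))
                msg <- c(msg, "adjacent intervals must have different labels")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Segmentation
#'
#' @param start,end interval bounds in seconds (must tile \code{[0, duration]}).
#' @param label interval labels, \code{"voice"} or \code{"silence"},
#'   alternating.
#' @param duration total duration in seconds; defaults to the last \code{end}.
#' @return A [Segmentation-class] object.
#' @export
segmentation <- function(start, end, label, duration = max(end)) {
    new("Segmentation", start = as.numeric(start), end = as.numeric(end),
        label = as.character(label), duration = as.numeric(duration))
}

#' Cohort speech-feature container
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"features"}
#' holding the fixed 160-dimensional session feature vector per participant
#' (rows = features, columns = participants), \code{rowData$type} giving the
#' feature type (\code{acoustic}/\code{prosodic}/\code{linguistic}, partition
#' 128/16/16) and participant covariates (\code{ucla}, \code{age},
#' \code{sex}) in \code{colData}.
#'
#' @seealso [speechFeatureSet()], [screenFeatures()], [runCV()]
#' @exportClass SpeechFeatureSet
setClass("SpeechFeatureSet", contains = "SummarizedExperiment")

setValidity("SpeechFeatureSet", function(object) {
    msg <- character()
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is required")
    fn <- speechFeatureNames()
    if (nrow(object) != length(fn$all))
        msg <- c(msg, sprintf("expected %d feature rows, got %d",
                              length(fn$all), nrow(object)))
    else if (!identical(rownames(object), fn$all))
        msg <- c(msg, "feature row names must equal speechFeatureNames()$all")
    if (!"type" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData must contain 'type'")
    cd <- SummarizedExperiment::colData(object)
    for (f in c("ucla", "age", "sex"))
        if (!f %in% colnames(cd)) msg <- c(msg, paste0("colData must contain '", f, "'"))
    if ("ucla" %in% colnames(cd)) {
        u <- cd$ucla
        if (any(!is.na(u) & (u < 20 | u > 80)))
            msg <- c(msg, "UCLA scores must lie in [20, 80]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SpeechFeatureSet
#'
#' @param features numeric matrix, 160 features x participants, with
#'   rownames equal to \code{speechFeatureNames()$all} (rows are reordered
#'   if necessary).
#' @param participants data.frame with one row per column of
#'   \code{features}, containing at least \code{ucla} (20--80), \code{age}
#'   and \code{sex}; a \code{participant_id} column is used for column
#'   names when present.
#' @return A [SpeechFeatureSet-class].
#' @export
speechFeatureSet <- function(features, participants) {
    fn <- speechFeatureNames()
    if (is.null(rownames(features)))
        stop("'features' must have feature row names")
    miss <- setdiff(fn$all, rownames(features))
    if (length(miss))
        stop("missing features: ", paste(head(miss, 5), collapse = ", "))
    features <- features[fn$all, , drop = FALSE]
    if (nrow(participants) != ncol(features))
        stop("participants rows must match feature columns")
    if ("participant_id" %in% colnames(participants))
        colnames(features) <- as.character(participants$participant_id)
    type <- rep(c("acoustic", "prosodic", "linguistic"),
                times = lengths(fn[c("acoustic", "prosodic", "linguistic")]))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = features),
        rowData = S4Vectors::DataFrame(type = type, row.names = fn$all),
        colData = S4Vectors::DataFrame(participants))
    new("SpeechFeatureSet", se)
}

#' Cross-validation evaluation report
#'
#' Result of [runCV()]: per-metric mean and 95\% confidence interval across
#' cross-validation iterations, plus (for classification) the mean pooled
#' confusion counts, the features selected in every fold, and the
#' per-iteration pooled test predictions.
#'
#' @slot task \code{"regression"} or \code{"classification"}.
#' @slot family model family used.
#' @slot metrics data.frame with columns metric, mean, lower, upper.
#' @slot perIteration numeric matrix, iterations x metrics.
#' @slot confusion named numeric (TP, FN, FP, TN) mean counts, or empty.
#' @slot selected list (one per iteration) of character vectors of
#'   selected feature names per fold.
#' @slot predictions numeric matrix, iterations x participants, pooled
#'   test-set predictions (class probabilities are not retained;
#'   classification predictions are 0/1).
#' @slot truth the target vector evaluated against.
#' @slot nIter,nFolds,seed protocol bookkeeping.
#' @exportClass EvalReport
setClass("EvalReport",
         representation(task = "character", family = "character",
                        metrics = "data.frame", perIteration = "matrix",
                        confusion = "numeric", selected = "list",
                        predictions = "matrix", truth = "numeric",
                        nIter = "integer", nFolds = "integer",
                        seed = "integer"))

setMethod("show", "AudioResponse", function(object) {
    cat(sprintf("AudioResponse: %.3f s at %g Hz (question %d)\n",
                length(object@samples) / object@rate, object@rate,
                object@questionId))
})

setMethod("show", "Segmentation", function(object) {
    v <- sum((object@end - object@start)[object@label == "voice"])
    cat(sprintf("Segmentation: %d intervals over %.3f s (%.3f s voiced)\n",
                length(object@start), object@duration, v))
})

setMethod("show", "EvalReport", function(object) {
    cat(sprintf("EvalReport: %s (%s), %d x %d-fold CV\n", object@task,
                object@family, object@nIter, object@nFolds))
    m <- object@metrics
    for (i in seq_len(nrow(m)))
        cat(sprintf("  %-12s %.3f [%.3f, %.3f]\n", m$metric[i], m$mean[i],
                    m$lower[i], m$upper[i]))
    if (length(object@confusion))
        cat("  confusion (mean counts): ",
            paste(names(object@confusion),
                  sprintf("%.2f", object@confusion), collapse = ", "), "\n")
})
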