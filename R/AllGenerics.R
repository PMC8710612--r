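#' Duration of a recording or segmentation, in seconds
#' @param x an [AudioResponse-class] or [Segmentation-class].
#' @return numeric scalar, seconds.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname duration
#' @export
setMethod("duration", "AudioResponse",
          function(x) length(x@samples) / x@rate)

#' @rdname duration
#' @export
setMethod("duration", "Segmentation", function(x) x@duration)

#' Accessors for AudioResponse
#' @param x an [AudioResponse-class].
#' @return \code{samples()}: the amplitude vector; \code{sampleRate()}: the
#'   rate in Hz; \code{questionId()}: the question index.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname samples
#' @export
setMethod("samples", "AudioResponse", function(x) x@samples)

#' @rdname samples
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname samples
#' @export
setMethod("sampleRate", "AudioResponse", function(x) x@rate)

#' @rdname samples
#' @export
setGeneric("questionId", function(x) standardGeneric("questionId"))

#' @rdname samples
#' @export
setMethod("questionId", "AudioResponse", function(x) x@questionId)

#' Intervals of a Segmentation as a data.frame
#' @param x a [Segmentation-class].
#' @return data.frame with columns \code{start}, \code{end}, \code{label}.
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname intervals
#' @export
setMethod("intervals", "Segmentation", function(x)
    data.frame(start = x@start, end = x@end, label = x@label))

#' UCLA Loneliness scores of a cohort
#' @param x a [SpeechFeatureSet-class].
#' @return integer vector of total scores (20--80), one per participant.
#' @export
setGeneric("uclaScores", function(x) standardGeneric("uclaScores"))

#' @rdname uclaScores
#' @export
setMethod("uclaScores", "SpeechFeatureSet",
          function(x) SummarizedExperiment::colData(x)$ucla)

#' Feature type annotation (acoustic / prosodic / linguistic)
#' @param x a [SpeechFeatureSet-class].
#' @return character vector parallel to the feature rows.
#' @export
setGeneric("featureType", function(x) standardGeneric("featureType"))

#' @rdname featureType
#' @export
setMethod("featureType", "SpeechFeatureSet",
          function(x) SummarizedExperiment::rowData(x)$type)

#' Feature matrix in modeling orientation (participants x features)
#' @param x a [SpeechFeatureSet-class].
#' @return numeric matrix with participants as rows.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "SpeechFeatureSet",
          function(x) t(SummarizedExperiment::assay(x, "features")))
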