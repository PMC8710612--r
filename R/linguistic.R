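# Transcript-side features: sentiment word counts on the four designated
# questions and filler-word proportion on all eight. The morphological
# analyzer is pluggable; the default tokenizer is whitespace splitting plus
# lowercasing with an identity lemmatizer, which is exact for the bundled
# synthetic-language generator.

#' Tokenize a transcript
#'
#' @param text a character string (possibly empty).
#' @param tokenizer either \code{"default"} (split on whitespace, lowercase)
#'   or a function \code{text -> character vector} supplied by the user,
#'   e.g. wrapping a real morphological analyzer with lemmatization.
#' @return character vector of tokens (empty for empty text).
#' @examples
#' tokenizeTranscript("Good trip  was GOOD")
#' @export
tokenizeTranscript <- function(text, tokenizer = "default") {
    if (is.function(tokenizer)) return(as.character(tokenizer(text)))
    stopifnot(identical(tokenizer, "default"))
    if (length(text) == 0L || !nzchar(trimws(text))) return(character(0))
    tolower(strsplit(trimws(text), "\\s+")[[1L]])
}

#' Count positive and negative words
#'
#' Token-occurrence counts (repeats count each time) against a sentiment
#' lexicon.
#'
#' @param tokens character vector of tokens.
#' @param lexicon named character vector mapping word to \code{"pos"} or
#'   \code{"neg"}; see [readSentimentLexicon()].
#' @return named integer vector \code{c(n_positive, n_negative)}.
#' @export
countSentiment <- function(tokens, lexicon) {
    stopifnot(!is.null(names(lexicon)), all(lexicon %in% c("pos", "neg")))
    if (anyDuplicated(names(lexicon)))
        stop("lexicon maps a word to both polarities or repeats a word")
    pol <- lexicon[tokens]
    c(n_positive = sum(pol == "pos", na.rm = TRUE),
      n_negative = sum(pol == "neg", na.rm = TRUE))
}

#' Proportion of filler words
#'
#' @param tokens character vector of tokens.
#' @param filler_set character vector of filler/hesitation words.
#' @return fraction of tokens that are fillers; 0 for an empty transcript.
#' @export
fillerProportion <- function(tokens, filler_set) {
    if (!length(tokens)) return(0)
    mean(tokens %in% filler_set)
}

#' Linguistic feature block of one session
#'
#' From the eight per-question transcripts: positive and negative word
#' counts on the four designated sentiment questions and filler proportion
#' on all eight, i.e. 2 x 4 + 1 x 8 = 16 features.
#'
#' @param transcripts list of 8 token vectors named \code{"1"}..\code{"8"}
#'   (or an unnamed list in question order).
#' @param lexicon sentiment lexicon (named vector, word -> "pos"/"neg").
#' @param filler_set character vector of filler words.
#' @param sentiment_questions the four question ids scored for sentiment
#'   (default 3, 6, 7, 8: fun childhood activity, earthquake plan, travel
#'   plan, traditional event).
#' @return named numeric vector of length 16 (\code{li.pos.q*},
#'   \code{li.neg.q*}, \code{li.filler.q*}).
#' @export
summarizeSessionLinguistics <- function(transcripts, lexicon, filler_set,
                                        sentiment_questions = c(3L, 6L, 7L, 8L)) {
    stopifnot(length(sentiment_questions) == 4L,
              all(sentiment_questions %in% 1:8))
    if (is.null(names(transcripts)) && length(transcripts) == 8L)
        names(transcripts) <- as.character(1:8)
    missing_q <- setdiff(as.character(1:8), names(transcripts))
    if (length(missing_q))
        stop("missing transcript for question ", missing_q[1L])
    sq <- sort(as.integer(sentiment_questions))
    out <- numeric(0)
    for (q in sq) {
        s <- countSentiment(transcripts[[as.character(q)]], lexicon)
        out[paste0("li.pos.q", q)] <- s[["n_positive"]]
        out[paste0("li.neg.q", q)] <- s[["n_negative"]]
    }
    for (q in 1:8)
        out[paste0("li.filler.q", q)] <-
            fillerProportion(transcripts[[as.character(q)]], filler_set)
    out
}

#' Read a sentiment lexicon file
#'
#' Expects a two-column TSV \code{word<TAB>pos|neg} with no header.
#'
#' @param path file path.
#' @return named character vector mapping word to polarity.
#' @export
readSentimentLexicon <- function(path) {
    tab <- read.delim(path, header = FALSE, col.names = c("word", "polarity"),
                      stringsAsFactors = FALSE)
    if (!all(tab$polarity %in% c("pos", "neg")))
        stop("lexicon polarities must be 'pos' or 'neg'")
    if (anyDuplicated(tab$word))
        stop("lexicon assigns a word more than once")
    setNames(tab$polarity, tab$word)
}

#' Read a filler-word list (one word per line)
#'
#' @param path file path.
#' @return character vector of filler words.
#' @export
readFillerList <- function(path) {
    w <- readLines(path, warn = FALSE)
    w[nzchar(trimws(w))]
}

#' Bundled toy lexicon and filler list
#'
#' A small synthetic-language sentiment lexicon and filler-word list used by
#' the cohort generator; real analyses supply their own dictionary files.
#'
#' @return \code{toyLexicon()}: named polarity vector;
#'   \code{toyFillerWords()}: character vector.
#' @export
toyLexicon <- function() {
    readSentimentLexicon(system.file("extdata", "toy_lexicon.tsv",
                                     package = "lonevox", mustWork = TRUE))
}

#' @rdname toyLexicon
#' @export
toyFillerWords <- function() {
    readFillerList(system.file("extdata", "toy_fillers.txt",
                               package = "lonevox", mustWork = TRUE))
}
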