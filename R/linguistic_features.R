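# Linguistic features of a timed transcript: words per minute, articulation
# rate, dysfluency, and sequential coherence.

#' Words per minute
#'
#' On the fixed 45 s task, WPM is defined as the total word count multiplied
#' by 0.75. A dimensional mode (`mode = "per_minute"`) computing
#' `word_count / (duration / 60)` is available; the choice only rescales a
#' feature that is z-standardized before analysis, so downstream inference is
#' unaffected. The mode used is recorded in the `"wpm_mode"` attribute.
#'
#' @param transcript A [timed_transcript()].
#' @param mode `"x0.75"` (default) or `"per_minute"`.
#' @return WPM as a single number, with attribute `wpm_mode`.
#' @export
compute_wpm <- function(transcript, mode = c("x0.75", "per_minute")) {
  mode <- match.arg(mode)
  n_words <- nrow(transcript$tokens)
  wpm <- if (mode == "x0.75") {
    n_words * 0.75
  } else {
    if (transcript$total_duration_s <= 0) stop("total_duration_s must be positive")
    n_words / (transcript$total_duration_s / 60)
  }
  attr(wpm, "wpm_mode") <- mode
  wpm
}

#' Actual speaking duration, excluding pauses
#'
#' @param transcript A [timed_transcript()].
#' @return Sum of token interval durations in seconds (0 if no tokens).
#' @export
speaking_duration <- function(transcript) {
  tok <- transcript$tokens
  if (nrow(tok) == 0) return(0)
  sum(tok$end_s - tok$start_s)
}

#' Articulation rate
#'
#' Total word count divided by the actual speech duration (excluding pauses),
#' in words per second.
#'
#' @param transcript A [timed_transcript()].
#' @return Articulation rate (words/s).
#' @export
compute_ar <- function(transcript) {
  dur <- speaking_duration(transcript)
  if (dur <= 0) stop("no speech: speaking duration is zero")
  nrow(transcript$tokens) / dur
}

#' Classify a pause duration
#'
#' Short pauses last less than 0.3 s; medium pauses from 0.3 s up to (but not
#' including) 0.7 s; long pauses 0.7 s or more. Boundaries are left-closed,
#' right-open.
#'
#' @param duration_s Pause duration in seconds (> 0).
#' @return `"short"`, `"medium"`, or `"long"`.
#' @export
classify_pause <- function(duration_s) {
  if (!is.finite(duration_s) || duration_s <= 0) stop("pause duration must be positive")
  if (duration_s < 0.3) "short" else if (duration_s < 0.7) "medium" else "long"
}

#' Flag interjection tokens
#'
#' When a part-of-speech tagger is supplied it decides: a token is an
#' interjection iff its tag equals `interjection_tag`. Without a tagger,
#' membership in a filled-pause lexicon (case-insensitive) is used.
#'
#' @param tokens Character vector of token texts.
#' @param tagger Optional function mapping a character vector of tokens to an
#'   equal-length character vector of part-of-speech tags.
#' @param lexicon Filled-pause word forms for the lexicon fallback.
#' @param interjection_tag Tag emitted by the tagger for interjections
#'   (default `"INTJ"`).
#' @return Logical vector, one flag per token.
#' @export
detect_interjections <- function(tokens, tagger = NULL,
                                 lexicon = filled_pause_lexicon(),
                                 interjection_tag = "INTJ") {
  if (length(tokens) == 0L) stop("tokens must be non-empty")
  if (!is.null(tagger)) {
    tags <- tagger(tokens)
    if (length(tags) != length(tokens)) {
      stop("tagger returned ", length(tags), " tags for ", length(tokens), " tokens")
    }
    return(tags == interjection_tag)
  }
  tolower(trimws(tokens)) %in% tolower(lexicon)
}

#' Dysfluency
#'
#' The ratio of short or medium pauses, together with the number of
#' interjections, to the total word count. Long pauses are excluded.
#' Interjection tokens count both as words (denominator) and as dysfluency
#' events (numerator), which keeps the ratio interpretable.
#'
#' @param transcript A [timed_transcript()].
#' @param tagger Optional part-of-speech tagger (see [detect_interjections()]).
#' @param lexicon Filled-pause lexicon for the fallback detector.
#' @return Dysfluency ratio (>= 0).
#' @export
compute_dysfluency <- function(transcript, tagger = NULL,
                               lexicon = filled_pause_lexicon()) {
  n_words <- nrow(transcript$tokens)
  if (n_words == 0) stop("dysfluency undefined for zero words")
  n_sm <- sum(transcript$pauses$class %in% c("short", "medium"))
  n_intj <- sum(detect_interjections(transcript$tokens$text, tagger, lexicon))
  (n_sm + n_intj) / n_words
}

#' Cosine similarities between adjacent words
#'
#' Looks each token up in the embedding table and returns the cosine
#' similarity of every consecutive in-vocabulary pair. Out-of-vocabulary
#' tokens are skipped (`oov_policy = "skip"`, the default, so similarities
#' bridge across removed tokens) or raise an error naming the word.
#'
#' @param tokens Character vector of token texts.
#' @param embeddings An [embedding_table()].
#' @param oov_policy `"skip"` or `"error"`.
#' @return Numeric vector of length (retained tokens - 1).
#' @export
adjacent_similarities <- function(tokens, embeddings, oov_policy = c("skip", "error")) {
  oov_policy <- match.arg(oov_policy)
  stopifnot(inherits(embeddings, "embedding_table"))
  key <- tolower(tokens)
  in_vocab <- key %in% rownames(embeddings$vectors)
  if (oov_policy == "error" && any(!in_vocab)) {
    stop("out-of-vocabulary word: '", tokens[which(!in_vocab)[1]], "'")
  }
  key <- key[in_vocab]
  if (length(key) < 2) stop("need at least 2 in-vocabulary tokens for similarities")
  V <- embeddings$vectors[key, , drop = FALSE]
  unname(rowSums(V[-nrow(V), , drop = FALSE] * V[-1, , drop = FALSE]))
}

#' Sequential coherence
#'
#' The adjacent-word cosine similarity sequence is smoothed with a centered
#' moving average of window `window` (the window shrinks at the edges), and SC
#' is the mean of the smoothed sequence. When the sequence is shorter than the
#' window this reduces to the plain mean.
#'
#' @param tokens Character vector of token texts.
#' @param embeddings An [embedding_table()].
#' @param window Moving-average window size (default 5).
#' @param oov_policy Passed to [adjacent_similarities()].
#' @return SC in \[-1, 1\].
#' @export
compute_sc <- function(tokens, embeddings, window = 5, oov_policy = c("skip", "error")) {
  sims <- adjacent_similarities(tokens, embeddings, oov_policy)
  mean(moving_average(sims, window))
}

# centered moving average with shrinking edges
moving_average <- function(x, window) {
  n <- length(x)
  if (n == 0) return(x)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Extract all four linguistic features
#'
#' @param transcript A [timed_transcript()].
#' @param embeddings An [embedding_table()] for sequential coherence.
#' @param tagger Optional part-of-speech tagger for interjection detection.
#' @param wpm_mode Passed to [compute_wpm()].
#' @param sc_window Passed to [compute_sc()].
#' @return A one-row data frame with columns `WPM`, `AR`, `Dysfluency`, `SC`.
#' @export
extract_linguistic <- function(transcript, embeddings, tagger = NULL,
                               wpm_mode = c("x0.75", "per_minute"), sc_window = 5) {
  wpm_mode <- match.arg(wpm_mode)
  if (nrow(transcript$tokens) < 2) stop("transcript must contain at least 2 words")
  data.frame(
    WPM = as.numeric(compute_wpm(transcript, wpm_mode)),
    AR = compute_ar(transcript),
    Dysfluency = compute_dysfluency(transcript, tagger),
    SC = compute_sc(transcript$tokens$text, embeddings, sc_window)
  )
}

# ---- Embedding table --------------------------------------------------------

#' Word-embedding table
#'
#' A dense word-to-vector map with unit-norm rows; the source of cosine
#' similarities for sequential coherence.
#'
#' @param vectors Numeric matrix, one row per word, row names = words
#'   (lowercase).
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) stop("duplicate vocabulary entries")
  norms <- sqrt(rowSums(vectors^2))
  if (any(abs(norms - 1) > 1e-6)) stop("embedding vectors must be unit-norm within 1e-6")
  structure(list(vectors = vectors), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words x %d dims\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Read an embedding table from plain text
#'
#' One word per line: `word v1 v2 ... vD`, whitespace-separated. Vectors are
#' renormalized to unit length on read.
#'
#' @param path Path to the text file.
#' @return An [embedding_table()].
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(parts[[1]]) - 1)))
  vecs <- vecs / sqrt(rowSums(vecs^2))
  rownames(vecs) <- tolower(words)
  embedding_table(vecs)
}

#' Write an embedding table as plain text
#'
#' @param embeddings An [embedding_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(inherits(embeddings, "embedding_table"))
  V <- embeddings$vectors
  lines <- vapply(seq_len(nrow(V)), function(i) {
    paste(c(rownames(V)[i], format(V[i, ], digits = 10, trim = TRUE)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
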