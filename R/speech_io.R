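# Readers/writers for the formats the pipeline touches (mono PCM WAV, Praat
# TextGrid) and construction of the internal timed-transcript representation.

#' Audio recording container
#'
#' Holds a mono waveform as amplitudes in \[-1, 1\] together with its sample
#' rate and the speaker's sex (the latter selects the sex-specific pitch
#' analysis band downstream).
#'
#' @param samples Numeric vector of amplitudes, each in \[-1, 1\].
#' @param sample_rate_hz Integer sampling rate, at least 8000 Hz.
#' @param speaker_sex `"female"` or `"male"`.
#' @return An object of class `audio_recording` with elements `samples`,
#'   `sample_rate_hz`, and `speaker_sex`.
#' @export
audio_recording <- function(samples, sample_rate_hz, speaker_sex = c("female", "male")) {
  speaker_sex <- match.arg(speaker_sex)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio recording must contain at least one sample")
  if (any(!is.finite(samples))) stop("audio samples must be finite")
  if (max(abs(samples)) > 1 + 1e-9) stop("audio samples must lie in [-1, 1]")
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz < 8000L) {
    stop("sample_rate_hz must be an integer >= 8000")
  }
  structure(
    list(samples = pmin(1, pmax(-1, samples)),
         sample_rate_hz = sample_rate_hz,
         speaker_sex = speaker_sex),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %.2f s @ %d Hz (%s speaker)\n",
              length(x$samples) / x$sample_rate_hz, x$sample_rate_hz, x$speaker_sex))
  invisible(x)
}

#' Duration of an audio recording in seconds
#' @param recording An [audio_recording()].
#' @return Duration in seconds.
#' @export
audio_duration <- function(recording) {
  length(recording$samples) / recording$sample_rate_hz
}

# ---- WAV (RIFF, PCM 16-bit, mono) -------------------------------------------
# No installed R package provides WAV I/O, so the (small) RIFF/PCM subset the
# pipeline needs is implemented directly with readBin/writeBin.

#' Write a recording to a 16-bit PCM mono WAV file
#'
#' @param recording An [audio_recording()].
#' @param path Output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path) {
  stopifnot(inherits(recording, "audio_recording"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  x <- recording$samples
  # symmetric 16-bit quantization; clip the single value +1 to 32767
  q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(recording$sample_rate_hz, con, size = 4, endian = "little")
  writeBin(recording$sample_rate_hz * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Only the format the pipeline writes is accepted: RIFF/WAVE, PCM encoding,
#' one channel, 16 bits per sample. Anything else raises an error naming the
#' offending encoding, rather than silently coercing.
#'
#' @param path Path to a WAV file.
#' @param speaker_sex Speaker sex attached to the returned recording.
#' @return An [audio_recording()].
#' @export
read_wav <- function(path, speaker_sex = c("female", "male")) {
  speaker_sex <- match.arg(speaker_sex)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      audio_format <- readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
      n_channels <- readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
      rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
      if (sz > 16) invisible(readBin(con, "raw", n = sz - 16L))
      if (audio_format != 1L) stop("unsupported WAV encoding (format tag ", audio_format,
                                   "): PCM required")
      if (n_channels != 1L) stop("mono required (file has ", n_channels, " channels)")
      if (bits != 16L) stop("unsupported WAV encoding (", bits, "-bit): 16-bit PCM required")
      fmt <- list(rate = rate)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      samples <- readBin(con, "integer", n = sz %/% 2L, size = 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", n = sz + (sz %% 2L)))  # skip (word-aligned)
    }
  }
  if (is.null(fmt) || is.null(samples)) stop("malformed WAV file: ", path)
  audio_recording(samples / 32768, fmt$rate, speaker_sex)
}

# ---- Praat TextGrid ---------------------------------------------------------

#' Write a word-level interval tier as a Praat TextGrid
#'
#' Writes the long ("full") text format, UTF-8, with a single interval tier.
#' Gaps between tokens become unlabeled intervals, as Praat does.
#'
#' @param transcript A [timed_transcript()].
#' @param path Output path.
#' @param tier_name Name of the interval tier (default `"words"`).
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(transcript, path, tier_name = "words") {
  stopifnot(inherits(transcript, "timed_transcript"))
  tok <- transcript$tokens
  total <- transcript$total_duration_s
  # interleave unlabeled gap intervals so the tier tiles [0, total]
  starts <- numeric(0); ends <- numeric(0); labels <- character(0)
  cursor <- 0
  for (i in seq_len(nrow(tok))) {
    if (tok$start_s[i] > cursor + 1e-9) {
      starts <- c(starts, cursor); ends <- c(ends, tok$start_s[i]); labels <- c(labels, "")
    }
    starts <- c(starts, tok$start_s[i]); ends <- c(ends, tok$end_s[i])
    labels <- c(labels, tok$text[i])
    cursor <- tok$end_s[i]
  }
  if (cursor < total - 1e-9) {
    starts <- c(starts, cursor); ends <- c(ends, total); labels <- c(labels, "")
  }
  if (length(starts) == 0L) { starts <- 0; ends <- total; labels <- "" }
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0 ",
    sprintf("xmax = %.6f ", total),
    "tiers? <exists> ",
    "size = 1 ",
    "item []: ",
    "    item [1]:",
    '        class = "IntervalTier" ',
    sprintf('        name = "%s" ', tier_name),
    "        xmin = 0 ",
    sprintf("        xmax = %.6f ", total),
    sprintf("        intervals: size = %d ", length(starts))
  )
  for (i in seq_along(starts)) {
    lines <- c(lines,
      sprintf("        intervals [%d]:", i),
      sprintf("            xmin = %.6f ", starts[i]),
      sprintf("            xmax = %.6f ", ends[i]),
      sprintf('            text = "%s" ', gsub('"', '""', labels[i])))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an interval tier from a Praat TextGrid
#'
#' Accepts both the long ("full") and the short text format. Returns the raw
#' labeled intervals of the requested tier in time order; empty-label
#' intervals (silences) are dropped.
#'
#' @param path Path to a TextGrid file.
#' @param word_tier_name Name of the interval tier to read (default
#'   `"words"`).
#' @return A list with `intervals` (data frame `start_s`, `end_s`, `text`) and
#'   `total_duration_s`.
#' @export
read_textgrid <- function(path, word_tier_name = "words") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))]))) {
    stop("not a Praat TextGrid file: ", path)
  }
  long_format <- any(grepl("^\\s*item\\s*\\[", lines))
  tg <- if (long_format) parse_textgrid_long(lines) else parse_textgrid_short(lines)
  tier_names <- vapply(tg$tiers, `[[`, character(1), "name")
  idx <- match(word_tier_name, tier_names)
  if (is.na(idx)) {
    stop("tier '", word_tier_name, "' not found; available tiers: ",
         paste(sprintf('"%s"', tier_names), collapse = ", "))
  }
  tier <- tg$tiers[[idx]]
  iv <- tier$intervals
  iv <- iv[order(iv$start_s), , drop = FALSE]
  if (nrow(iv) > 1 && any(iv$start_s[-1] < iv$end_s[-nrow(iv)] - 1e-6)) {
    stop("overlapping intervals in tier '", word_tier_name, "'")
  }
  iv <- iv[trimws(iv$text) != "", , drop = FALSE]
  rownames(iv) <- NULL
  list(intervals = iv, total_duration_s = tg$xmax)
}

# long-format parser: key = value lines with indentation
parse_textgrid_long <- function(lines) {
  num_of <- function(l) as.numeric(sub("^.*=\\s*", "", l))
  str_of <- function(l) {
    s <- sub('^[^"]*"', "", l)
    s <- sub('"\\s*$', "", s)
    gsub('""', '"', s)
  }
  xmax <- NA_real_
  tiers <- list()
  cur <- NULL
  i <- 1L
  n <- length(lines)
  # global xmax is the first xmax line before any item
  while (i <= n) {
    l <- lines[i]
    if (grepl("^\\s*item\\s*\\[\\s*\\d+\\s*\\]", l)) break
    if (grepl("^\\s*xmax\\s*=", l)) xmax <- num_of(l)
    i <- i + 1L
  }
  while (i <= n) {
    l <- lines[i]
    if (grepl("^\\s*item\\s*\\[\\s*\\d+\\s*\\]", l)) {
      if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- finish_tier(cur)
      cur <- list(class = NA_character_, name = NA_character_,
                  starts = numeric(0), ends = numeric(0), texts = character(0))
    } else if (!is.null(cur)) {
      if (grepl("^\\s*class\\s*=", l)) cur$class <- str_of(l)
      else if (grepl("^\\s*name\\s*=", l)) cur$name <- str_of(l)
      else if (grepl("^\\s*intervals\\s*\\[", l)) {
        xmin_l <- lines[i + 1L]; xmax_l <- lines[i + 2L]; text_l <- lines[i + 3L]
        cur$starts <- c(cur$starts, num_of(xmin_l))
        cur$ends <- c(cur$ends, num_of(xmax_l))
        cur$texts <- c(cur$texts, str_of(text_l))
        i <- i + 3L
      }
    }
    i <- i + 1L
  }
  if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- finish_tier(cur)
  tiers <- Filter(function(t) identical(t$class, "IntervalTier"), tiers)
  list(xmax = xmax, tiers = tiers)
}

# short-format parser: values appear positionally, one per line
parse_textgrid_short <- function(lines) {
  body <- trimws(lines[-(1:2)])
  body <- body[body != ""]
  # drop a possible "<exists>" flag line
  body <- body[!grepl("<exists>", body, fixed = TRUE)]
  xmin <- as.numeric(body[1]); xmax <- as.numeric(body[2])
  n_tiers <- as.integer(body[3])
  pos <- 4L
  unquote <- function(s) gsub('""', '"', sub('"\\s*$', "", sub('^\\s*"', "", s)))
  tiers <- list()
  for (t in seq_len(n_tiers)) {
    cls <- unquote(body[pos]); nm <- unquote(body[pos + 1L])
    pos <- pos + 4L  # class, name, tier xmin, tier xmax
    n_iv <- as.integer(body[pos - 1L + 1L]); pos <- pos + 1L
    starts <- numeric(n_iv); ends <- numeric(n_iv); texts <- character(n_iv)
    for (j in seq_len(n_iv)) {
      starts[j] <- as.numeric(body[pos]); ends[j] <- as.numeric(body[pos + 1L])
      texts[j] <- unquote(body[pos + 2L])
      pos <- pos + 3L
    }
    if (identical(cls, "IntervalTier")) {
      tiers[[length(tiers) + 1L]] <-
        finish_tier(list(class = cls, name = nm, starts = starts, ends = ends, texts = texts))
    }
  }
  list(xmax = xmax, tiers = tiers)
}

finish_tier <- function(cur) {
  list(class = cur$class, name = cur$name,
       intervals = data.frame(start_s = cur$starts, end_s = cur$ends,
                              text = cur$texts, stringsAsFactors = FALSE))
}

# ---- Timed transcript -------------------------------------------------------

#' Timed transcript container
#'
#' Ordered word tokens with start/end times plus the classified inter-token
#' pauses; the substrate for all linguistic features. Intervals follow the
#' closed-open convention `[start, end)` in seconds.
#'
#' @param tokens Data frame with columns `text`, `start_s`, `end_s` and
#'   optionally `is_interjection` (logical).
#' @param pauses Data frame with columns `start_s`, `end_s`, `class`
#'   (`"short"`, `"medium"`, `"long"`). Usually derived, not supplied.
#' @param total_duration_s Total task duration in seconds.
#' @return An object of class `timed_transcript`.
#' @export
timed_transcript <- function(tokens, pauses = NULL, total_duration_s) {
  stopifnot(is.data.frame(tokens))
  if (nrow(tokens) > 0) {
    if (is.null(tokens$is_interjection)) tokens$is_interjection <- FALSE
    tokens <- tokens[order(tokens$start_s), , drop = FALSE]
    rownames(tokens) <- NULL
    if (any(tokens$end_s <= tokens$start_s)) stop("token intervals must have end > start")
    if (any(tokens$start_s < -1e-9) || any(tokens$end_s > total_duration_s + 1e-9)) {
      stop("token interval outside [0, total_duration_s]")
    }
    if (nrow(tokens) > 1 &&
        any(tokens$start_s[-1] < tokens$end_s[-nrow(tokens)] - 1e-9)) {
      stop("token intervals must not overlap")
    }
  } else {
    tokens <- data.frame(text = character(0), start_s = numeric(0),
                         end_s = numeric(0), is_interjection = logical(0))
  }
  if (is.null(pauses)) {
    pauses <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         class = character(0), stringsAsFactors = FALSE)
  }
  structure(
    list(tokens = tokens, pauses = pauses, total_duration_s = total_duration_s),
    class = "timed_transcript"
  )
}

#' @export
print.timed_transcript <- function(x, ...) {
  cat(sprintf("<timed_transcript> %d tokens, %d pauses over %.2f s\n",
              nrow(x$tokens), nrow(x$pauses), x$total_duration_s))
  invisible(x)
}

#' Build a timed transcript from raw labeled intervals
#'
#' Labeled intervals become tokens; gaps of at least `min_gap_s` between
#' consecutive tokens become pauses, classified into short/medium/long by
#' [classify_pause()]. Leading and trailing silence is not counted as a pause:
#' dysfluency is defined on within-speech pausing, and a slow starter should
#' not accrue pauses before speaking.
#'
#' @param intervals Data frame with columns `start_s`, `end_s`, `text`,
#'   ordered and non-overlapping.
#' @param total_duration_s Task duration in seconds.
#' @param min_gap_s Minimum silence counted as a pause (default 0.05 s, well
#'   below the shortest analyzed pause class boundary of 0.3 s).
#' @param interjection_lexicon Character vector of filled-pause word forms
#'   used to flag interjection tokens (case-insensitive); defaults to the
#'   packaged lexicon.
#' @return A [timed_transcript()].
#' @export
transcript_from_intervals <- function(intervals, total_duration_s,
                                      min_gap_s = 0.05,
                                      interjection_lexicon = filled_pause_lexicon()) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) > 0) {
    intervals <- intervals[order(intervals$start_s), , drop = FALSE]
    if (any(intervals$end_s > total_duration_s + 1e-9)) {
      stop("interval exceeds total_duration_s")
    }
    if (nrow(intervals) > 1 &&
        any(intervals$start_s[-1] < intervals$end_s[-nrow(intervals)] - 1e-9)) {
      stop("intervals must be non-overlapping")
    }
  }
  tokens <- data.frame(
    text = as.character(intervals$text),
    start_s = intervals$start_s,
    end_s = intervals$end_s,
    stringsAsFactors = FALSE
  )
  tokens$is_interjection <- tolower(trimws(tokens$text)) %in% tolower(interjection_lexicon)
  pauses <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       class = character(0), stringsAsFactors = FALSE)
  if (nrow(tokens) > 1) {
    gaps_start <- tokens$end_s[-nrow(tokens)]
    gaps_end <- tokens$start_s[-1]
    keep <- (gaps_end - gaps_start) >= min_gap_s
    if (any(keep)) {
      d <- gaps_end[keep] - gaps_start[keep]
      pauses <- data.frame(
        start_s = gaps_start[keep], end_s = gaps_end[keep],
        class = vapply(d, classify_pause, character(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  timed_transcript(tokens, pauses, total_duration_s)
}

#' Packaged filled-pause lexicon
#'
#' Word forms treated as filled pauses (interjections) when no part-of-speech
#' tagger is supplied.
#'
#' @return Character vector of lowercase filled-pause forms.
#' @export
filled_pause_lexicon <- function() {
  path <- system.file("extdata", "filled_pauses.txt", package = "uhrspeech")
  if (nzchar(path)) readLines(path, warn = FALSE) else
    c("um", "uh", "erm", "er", "ah", "hmm", "mm", "eh")
}
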