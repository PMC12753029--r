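# Synthetic speech-cohort generator: participants with covariates and outcome
# labels, timed transcripts, voiced audio, Likert rater items, and toy word
# embeddings, with controllable group effects so downstream stages have known
# ground truth.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generator determinism never perturbs user randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort generator configuration
#'
#' Defaults emulate the study conditions: outcome group sizes 12 converted /
#' 15 remitted / 14 maintained; a 45 s task; covariate marginals on the scale
#' of the cohort's demographic table (for example BAI mean about 17, SD about
#' 13, about 68% male); and group effects, in SD units of the corresponding
#' generative parameter, matching the reported contrasts (converted vs
#' remitted: word count -1.17 SD, pause and interjection rates +1.39 SD;
#' maintained vs remitted: word count -0.79 SD; no acoustic group effects).
#'
#' @param group_sizes Named integer vector over
#'   `c("converted", "remitted", "maintained")`.
#' @param effect_spec Named list (one entry per outcome group) of per-group
#'   shifts in SD units, each a list with any of `word_count`, `pause_rate`,
#'   `interjection_rate`, `f0_level`, `intensity_level`.
#' @param covariate_spec List with `sex_male_p`, `bacs_mean`, `bacs_sd`,
#'   `bai_mean`, `bai_sd`, `dd_prev`.
#' @param speech_spec List controlling transcript generation (word-count
#'   mean/SD/floor, log-normal word durations, pause and interjection rates,
#'   pause-duration mixture, cluster-switch probability).
#' @param voice_spec List controlling audio synthesis (sex-specific base F0,
#'   between-speaker F0 SD, within-utterance F0 SD, amplitude, spectral tilt
#'   in dB/octave, noise floor in dB, sample rate).
#' @param rating_spec List with `outcome_assoc` (association of item means
#'   with outcome severity), `rater_noise_sd`, `item_sd`.
#' @param task_duration_s Task duration in seconds (default 45).
#' @param seed Integer seed; same config + seed reproduces every artifact
#'   bit-identically.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(converted = 12, remitted = 15, maintained = 14),
                          effect_spec = default_effect_spec(),
                          covariate_spec = list(),
                          speech_spec = list(),
                          voice_spec = list(),
                          rating_spec = list(),
                          task_duration_s = 45,
                          seed = 1L) {
  groups <- c("converted", "remitted", "maintained")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% groups)) {
    stop("group_sizes must be named with outcomes among: ", paste(groups, collapse = ", "))
  }
  sizes <- stats::setNames(integer(3), groups)
  sizes[names(group_sizes)] <- as.integer(group_sizes)
  if (any(sizes < 0)) stop("group sizes must be non-negative")
  if (sum(sizes) == 0) stop("empty cohort: all group sizes are zero")
  if (task_duration_s <= 0) stop("task_duration_s must be positive")

  cov_def <- list(sex_male_p = 0.68, bacs_mean = 57, bacs_sd = 12,
                  bai_mean = 17, bai_sd = 13, dd_prev = 0.27)
  sp_def <- list(word_count_mean = 110, word_count_sd = 22, word_count_floor = 5,
                 word_dur_meanlog = log(0.25), word_dur_sdlog = 0.30,
                 pause_prob_mean = 0.25, pause_prob_sd = 0.08,
                 interjection_prob_mean = 0.05, interjection_prob_sd = 0.03,
                 pause_mix = c(short = 0.50, medium = 0.35, long = 0.15),
                 lead_silence_range = c(0.3, 1.0),
                 cluster_switch_prob = 0.2)
  vo_def <- list(female_f0_hz = 200, male_f0_hz = 120, f0_between_sd_hz = 12,
                 f0_sd_hz = 8, amplitude = 0.3, amplitude_between_sd_db = 2,
                 spectral_tilt_db_per_octave = -9, noise_floor_db = 0,
                 sample_rate_hz = 16000L)
  rt_def <- list(outcome_assoc = 0.8, rater_noise_sd = 0.5, item_sd = 0.7)
  eff <- default_effect_spec()
  for (g in names(effect_spec)) eff[[g]] <- utils::modifyList(eff[[g]], effect_spec[[g]])

  structure(list(
    group_sizes = sizes,
    effect_spec = eff,
    covariate_spec = utils::modifyList(cov_def, covariate_spec),
    speech_spec = utils::modifyList(sp_def, speech_spec),
    voice_spec = utils::modifyList(vo_def, voice_spec),
    rating_spec = utils::modifyList(rt_def, rating_spec),
    task_duration_s = task_duration_s,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default per-group effect shifts (SD units)
#'
#' Emulates the reported group differences: the converted group speaks fewer
#' words and pauses/fills more than the remitted group; the maintained group
#' speaks somewhat fewer words; acoustic levels show no group effect.
#'
#' @return Named list of per-group shift lists.
#' @export
default_effect_spec <- function() {
  zero <- list(word_count = 0, pause_rate = 0, interjection_rate = 0,
               f0_level = 0, intensity_level = 0)
  list(
    converted = utils::modifyList(zero, list(word_count = -1.17, pause_rate = 1.39,
                                             interjection_rate = 1.39)),
    remitted = zero,
    maintained = utils::modifyList(zero, list(word_count = -0.79))
  )
}

#' Null effect configuration (all shifts zero)
#' @return Named list of per-group all-zero shift lists.
#' @export
null_effect_spec <- function() {
  zero <- list(word_count = 0, pause_rate = 0, interjection_rate = 0,
               f0_level = 0, intensity_level = 0)
  list(converted = zero, remitted = zero, maintained = zero)
}

#' Generate participants with covariates and outcome labels
#'
#' Covariates are drawn from the configured marginals, identically across
#' groups (the emulated cohort showed no significant covariate differences).
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `id`, `outcome`, `sex`, `DD`, `BACS`,
#'   `BAI`; one row per participant; deterministic under the config seed.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- sum(config$group_sizes)
    outcome <- rep(names(config$group_sizes), times = config$group_sizes)
    cv <- config$covariate_spec
    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      outcome = factor(outcome, levels = c("remitted", "converted", "maintained")),
      sex = factor(ifelse(stats::rbinom(n, 1, cv$sex_male_p) == 1, "male", "female"),
                   levels = c("female", "male")),
      DD = stats::rbinom(n, 1, cv$dd_prev),
      BACS = stats::rnorm(n, cv$bacs_mean, cv$bacs_sd),
      BAI = pmax(0, stats::rnorm(n, cv$bai_mean, cv$bai_sd)),
      stringsAsFactors = FALSE
    )
  })
}

#' Packaged synthetic vocabulary with topic clusters
#'
#' @return Data frame with columns `word` and `cluster`.
#' @export
synthetic_vocabulary <- function() {
  path <- system.file("extdata", "vocabulary.tsv", package = "uhrspeech")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Synthesize a timed transcript for one participant
#'
#' Word count, pause rate, and interjection rate are drawn from distributions
#' shifted by the participant's outcome-group effects (in SD units of each
#' generative parameter). Word durations are log-normal (median 0.25 s);
#' inter-word gaps come from a short/medium/long mixture so every pause class
#' occurs; interjections are realized as tokens from the packaged filled-pause
#' lexicon. Consumes the current RNG state; seed externally (for example with
#' [with_seed()]) for reproducibility.
#'
#' @param participant One row of [generate_cohort()] output.
#' @param config A [cohort_config()].
#' @return A [timed_transcript()].
#' @export
synthesize_transcript <- function(participant, config) {
  stopifnot(inherits(config, "cohort_config"))
  grp <- as.character(participant$outcome)
  eff <- config$effect_spec[[grp]]
  if (is.null(eff)) stop("participant outcome '", grp, "' not in configured groups")
  sp <- config$speech_spec

  n_words <- round(stats::rnorm(1, sp$word_count_mean + eff$word_count * sp$word_count_sd,
                                sp$word_count_sd))
  if (n_words < sp$word_count_floor) {
    warning("drawn word count ", n_words, " below floor; clipped to ",
            sp$word_count_floor)
    n_words <- sp$word_count_floor
  }
  p_pause <- min(0.9, max(0, stats::rnorm(1, sp$pause_prob_mean + eff$pause_rate * sp$pause_prob_sd,
                                          sp$pause_prob_sd / 2)))
  p_intj <- min(0.6, max(0, stats::rnorm(1, sp$interjection_prob_mean +
                                           eff$interjection_rate * sp$interjection_prob_sd,
                                         sp$interjection_prob_sd / 2)))

  lex <- filled_pause_lexicon()
  vocab <- synthetic_vocabulary()
  clusters <- unique(vocab$cluster)
  texts <- character(n_words)
  cl <- sample(clusters, 1)
  for (i in seq_len(n_words)) {
    if (stats::runif(1) < p_intj) {
      texts[i] <- sample(lex, 1)
    } else {
      if (stats::runif(1) < sp$cluster_switch_prob) cl <- sample(clusters, 1)
      texts[i] <- sample(vocab$word[vocab$cluster == cl], 1)
    }
  }

  durs <- stats::rlnorm(n_words, sp$word_dur_meanlog, sp$word_dur_sdlog)
  gaps <- numeric(n_words - 1L)
  if (n_words > 1) {
    has_pause <- stats::runif(n_words - 1L) < p_pause
    cls <- sample(names(sp$pause_mix), n_words - 1L, replace = TRUE, prob = sp$pause_mix)
    gaps <- ifelse(has_pause,
                   ifelse(cls == "short", stats::runif(n_words - 1L, 0.06, 0.299),
                          ifelse(cls == "medium", stats::runif(n_words - 1L, 0.3, 0.699),
                                 stats::runif(n_words - 1L, 0.7, 1.4))),
                   0)
  }
  lead <- stats::runif(1, sp$lead_silence_range[1], sp$lead_silence_range[2])
  total_speech <- sum(durs) + sum(gaps)
  budget <- config$task_duration_s - lead - 0.1
  if (total_speech > budget) {
    scale <- budget / total_speech
    durs <- durs * scale
    gaps <- gaps * scale
  }
  starts <- lead + c(0, cumsum(durs[-n_words] + gaps))[seq_len(n_words)]
  ends <- starts + durs
  intervals <- data.frame(start_s = starts, end_s = ends, text = texts,
                          stringsAsFactors = FALSE)
  transcript_from_intervals(intervals, config$task_duration_s,
                            interjection_lexicon = lex)
}

#' Per-participant voice profile
#'
#' Builds the voice parameters for [synthesize_audio()] from the participant's
#' sex and outcome-group acoustic effects. Base F0 stays inside the
#' sex-specific analysis band. Consumes the current RNG state.
#'
#' @param participant One row of [generate_cohort()] output.
#' @param config A [cohort_config()].
#' @return Named list of voice parameters.
#' @export
voice_profile <- function(participant, config) {
  vo <- config$voice_spec
  eff <- config$effect_spec[[as.character(participant$outcome)]]
  sex <- as.character(participant$sex)
  base <- if (sex == "female") vo$female_f0_hz else vo$male_f0_hz
  f0 <- base + eff$f0_level * vo$f0_between_sd_hz + stats::rnorm(1, 0, vo$f0_between_sd_hz)
  band <- pitch_band(sex)
  f0 <- min(band[2] - 10, max(band[1] + 5, f0))
  amp_db <- eff$intensity_level * vo$amplitude_between_sd_db +
    stats::rnorm(1, 0, vo$amplitude_between_sd_db)
  list(f0_base_hz = f0, f0_sd_hz = vo$f0_sd_hz,
       amplitude = min(0.95, vo$amplitude * 10^(amp_db / 20)),
       spectral_tilt_db_per_octave = vo$spectral_tilt_db_per_octave,
       noise_floor_db = vo$noise_floor_db,
       speaker_sex = sex)
}

#' Synthesize voiced audio for a timed transcript
#'
#' Produces a harmonic pulse-like signal (summed harmonics with a configurable
#' spectral tilt) during token intervals and near-silence (a low pink-noise
#' floor) during pauses, with a slowly varying F0 contour of the requested SD.
#' This yields controllable F0, intensity, and HF500 simultaneously; the audio
#' is deliberately unintelligible. Consumes the current RNG state.
#'
#' @param transcript A [timed_transcript()].
#' @param voice List with `f0_base_hz`, `f0_sd_hz`, `amplitude`,
#'   `spectral_tilt_db_per_octave`, `noise_floor_db` (dB, may be `-Inf` for
#'   exact silence), `speaker_sex`.
#' @param sample_rate_hz Sampling rate, at least 8000 Hz.
#' @return An [audio_recording()] whose duration equals the transcript
#'   duration.
#' @export
synthesize_audio <- function(transcript, voice, sample_rate_hz = 16000) {
  stopifnot(inherits(transcript, "timed_transcript"))
  fs <- as.integer(sample_rate_hz)
  if (fs < 8000L) stop("sample_rate_hz must be at least 8000")
  if (voice$f0_base_hz >= fs / 4) {
    stop("f0_base_hz (", voice$f0_base_hz, ") must be below a quarter of the ",
         "sampling rate (", fs / 4, " Hz)")
  }
  n <- round(transcript$total_duration_s * fs)
  t_idx <- seq_len(n)

  # slowly varying F0 contour: smooth noise, mean-centered, scaled to f0_sd
  f0 <- rep(voice$f0_base_hz, n)
  if (voice$f0_sd_hz > 0) {
    n_ctrl <- max(4L, ceiling(transcript$total_duration_s / 0.25))
    ctrl <- stats::rnorm(n_ctrl)
    contour <- stats::spline(seq(0, n, length.out = n_ctrl), ctrl, n = n)$y
    contour <- contour - mean(contour)
    s <- stats::sd(contour)
    if (s > 0) contour <- contour / s
    f0 <- voice$f0_base_hz + voice$f0_sd_hz * contour
  }
  f0 <- pmax(30, f0)
  phase <- 2 * pi * cumsum(f0) / fs

  tilt <- voice$spectral_tilt_db_per_octave
  k_max <- max(1L, floor(0.45 * fs / max(f0)))
  amps <- 10^(tilt * log2(seq_len(k_max)) / 20)
  sig <- numeric(n)
  for (k in seq_len(k_max)) sig <- sig + amps[k] * sin(k * phase)
  sig <- sig / sum(amps) * voice$amplitude

  # voiced mask with 5 ms raised-cosine edges at token boundaries
  mask <- numeric(n)
  edge <- max(2L, round(0.005 * fs))
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(edge) / edge)
  for (i in seq_len(nrow(transcript$tokens))) {
    a <- max(1L, round(transcript$tokens$start_s[i] * fs) + 1L)
    b <- min(n, round(transcript$tokens$end_s[i] * fs))
    if (b <= a) next
    mask[a:b] <- 1
    ra <- a:min(b, a + edge - 1L)
    mask[ra] <- pmin(mask[ra], ramp[seq_along(ra)])
    rb <- max(a, b - edge + 1L):b
    mask[rb] <- pmin(mask[rb], rev(ramp)[seq_along(rb)])
  }
  x <- sig * mask

  if (is.finite(voice$noise_floor_db)) {
    rms <- sqrt(4e-10 * 10^(voice$noise_floor_db / 10))
    noise <- stats::rnorm(n)
    # pink-ish shaping: 1/sqrt(f) amplitude in the frequency domain
    spec <- stats::fft(noise)
    f <- c(1, seq_len(n - 1))
    f <- pmin(f, n - f + 1)
    spec <- spec / sqrt(f)
    noise <- Re(stats::fft(spec, inverse = TRUE)) / n
    noise <- noise / stats::sd(noise) * rms
    x <- x + noise
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  audio_recording(x, fs, voice$speaker_sex)
}

#' Names of the 16 rated Likert items
#'
#' The first four are the verbal-expression subset used by the `HiSoC_ve`
#' feature set.
#'
#' @return Character vector of 16 item names.
#' @export
hisoc_item_names <- function() {
  c("verbal_expression", "clear_communication", "fluency_of_speech",
    "social_anxiety", "affect_range", "emotional_expression", "eye_contact",
    "facial_expression", "gesturing", "posture", "engagement", "confidence",
    "content_organization", "humor", "likability", "overall_impression")
}

#' Verbal-expression item subset
#' @return Character vector of the 4 verbal item names.
#' @export
hisoc_ve_items <- function() hisoc_item_names()[1:4]

#' Synthesize rater item scores for one participant
#'
#' Two raters score 16 items on a 1-5 Likert scale. A participant-level latent
#' trait decreases with outcome severity (remitted < maintained < converted)
#' in proportion to `outcome_assoc`; items add item-level noise shared across
#' raters, and each rater adds independent noise before rounding and clamping.
#' With `rater_noise_sd = 0` the two raters agree exactly. Consumes the
#' current RNG state.
#'
#' @param participant One row of [generate_cohort()] output.
#' @param config A [cohort_config()].
#' @return A 16 x 2 integer matrix (items x raters) of scores in 1..5, with
#'   item names as row names; class `hisoc_ratings`.
#' @export
synthesize_ratings <- function(participant, config) {
  rt <- config$rating_spec
  sev <- switch(as.character(participant$outcome),
                remitted = 0, maintained = 0.6, converted = 1,
                stop("unknown outcome"))
  latent <- 3.4 - 1.6 * rt$outcome_assoc * sev + stats::rnorm(1, 0, 0.5)
  item_latent <- latent + stats::rnorm(16, 0, rt$item_sd)
  scores <- vapply(1:2, function(r) {
    raw <- item_latent + stats::rnorm(16, 0, rt$rater_noise_sd)
    as.integer(pmin(5, pmax(1, round(raw))))
  }, integer(16))
  dimnames(scores) <- list(hisoc_item_names(), c("rater1", "rater2"))
  class(scores) <- c("hisoc_ratings", class(scores))
  scores
}

#' Build a toy word-embedding table with cluster structure
#'
#' Each cluster gets an (orthogonalized) unit center; word vectors mix the
#' center with a random orthogonal perturbation so that within-cluster
#' pairwise cosine similarity stays above `cohesion_floor` while
#' between-cluster similarity is near zero. Vectors are unit-norm.
#'
#' @param vocab Character vector of distinct words.
#' @param dim Embedding dimension (>= 2 and >= number of clusters).
#' @param clusters Cluster label per word (defaults to one cluster).
#' @param cohesion_floor Within-cluster cosine floor (default 0.85).
#' @param seed Integer seed.
#' @return An [embedding_table()].
#' @export
build_toy_embeddings <- function(vocab, dim = 16, clusters = NULL,
                                 cohesion_floor = 0.85, seed = 1L) {
  if (length(vocab) == 0) stop("vocab must be non-empty")
  if (anyDuplicated(vocab)) {
    stop("duplicate vocabulary entries: ", paste(unique(vocab[duplicated(vocab)]), collapse = ", "))
  }
  if (dim < 2) stop("dim must be at least 2")
  if (is.null(clusters)) clusters <- rep(1L, length(vocab))
  stopifnot(length(clusters) == length(vocab))
  cl_ids <- unique(clusters)
  if (dim <= length(cl_ids)) stop("dim must exceed the number of clusters")
  with_seed(seed, {
    centers <- qr.Q(qr(matrix(stats::rnorm(dim * length(cl_ids)), dim)))[, seq_along(cl_ids), drop = FALSE]
    a <- 0.5 * (1 + cohesion_floor)  # center weight: pairwise cosine ~ a
    V <- matrix(0, length(vocab), dim)
    for (i in seq_along(vocab)) {
      cvec <- centers[, match(clusters[i], cl_ids)]
      u <- stats::rnorm(dim)
      # orthogonal to the span of all centers, so between-cluster cosines
      # reduce to the (1 - a)-weighted noise term
      u <- u - drop(centers %*% crossprod(centers, u))
      u <- u / sqrt(sum(u^2))
      v <- sqrt(a) * cvec + sqrt(1 - a) * u
      V[i, ] <- v / sqrt(sum(v^2))
    }
    rownames(V) <- tolower(vocab)
    embedding_table(V)
  })
}

#' Simulate a complete cohort in memory
#'
#' Generates participants, transcripts, ratings, toy embeddings over the
#' packaged vocabulary plus the filled-pause lexicon, and (optionally) audio
#' recordings, all deterministically from the config seed.
#'
#' @param config A [cohort_config()].
#' @param audio Generate audio recordings (slower); default `TRUE`.
#' @return List with `participants` (data frame including 32 rating columns
#'   `<item>_r1/_r2`), `transcripts` (named list), `recordings` (named list or
#'   `NULL`), `ratings` (named list of matrices), and `embeddings`.
#' @export
simulate_cohort <- function(config, audio = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  participants <- generate_cohort(config)
  vocab <- synthetic_vocabulary()
  lex <- filled_pause_lexicon()
  embeddings <- build_toy_embeddings(
    c(vocab$word, lex), dim = 16,
    clusters = c(vocab$cluster, rep("filler", length(lex))),
    seed = config$seed + 1L
  )
  with_seed(config$seed + 2L, {
    transcripts <- list()
    recordings <- if (audio) list() else NULL
    ratings <- list()
    for (i in seq_len(nrow(participants))) {
      p <- participants[i, ]
      transcripts[[p$id]] <- synthesize_transcript(p, config)
      if (audio) {
        vp <- voice_profile(p, config)
        recordings[[p$id]] <- synthesize_audio(transcripts[[p$id]], vp,
                                               config$voice_spec$sample_rate_hz)
      }
      ratings[[p$id]] <- synthesize_ratings(p, config)
    }
    rating_cols <- do.call(rbind, lapply(ratings, function(m) {
      stats::setNames(c(m[, 1], m[, 2]),
                      c(paste0(rownames(m), "_r1"), paste0(rownames(m), "_r2")))
    }))
    participants <- cbind(participants, as.data.frame(rating_cols))
    rownames(participants) <- NULL
    list(participants = participants, transcripts = transcripts,
         recordings = recordings, ratings = ratings, embeddings = embeddings)
  })
}
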