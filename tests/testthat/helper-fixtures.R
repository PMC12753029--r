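# Shared fixtures, built in code at test time.

# pure sinusoid as an audio recording
make_tone <- function(freq_hz, dur_s = 1, fs = 16000, amp = 0.5, sex = "male") {
  t <- seq_len(round(dur_s * fs)) - 1
  audio_recording(amp * sin(2 * pi * freq_hz * t / fs), fs, sex)
}

# fully voiced synthetic recording: one token spanning (almost) the whole file
make_voiced <- function(f0 = 150, dur_s = 2, fs = 16000, sex = "male",
                        f0_sd = 0, amp = 0.3, tilt = -9, noise_db = -Inf,
                        seed = 1) {
  tx <- timed_transcript(
    data.frame(text = "a", start_s = 0, end_s = dur_s),
    total_duration_s = dur_s
  )
  voice <- list(f0_base_hz = f0, f0_sd_hz = f0_sd, amplitude = amp,
                spectral_tilt_db_per_octave = tilt, noise_floor_db = noise_db,
                speaker_sex = sex)
  with_seed(seed, synthesize_audio(tx, voice, fs))
}

# hand-built transcript from token intervals (+ derived pauses)
make_transcript <- function(starts, ends, texts = NULL, total = max(ends) + 0.5) {
  if (is.null(texts)) texts <- paste0("w", seq_along(starts))
  transcript_from_intervals(
    data.frame(start_s = starts, end_s = ends, text = texts,
               stringsAsFactors = FALSE),
    total_duration_s = total
  )
}

# embedding table from explicit (unnormalized) vectors
make_embeddings <- function(words, vectors) {
  V <- vectors / sqrt(rowSums(vectors^2))
  rownames(V) <- words
  embedding_table(V)
}

# covariate frame with a given outcome layout and noise-free covariates
make_covariates <- function(outcome, seed = 1) {
  with_seed(seed, data.frame(
    DD = stats::rbinom(length(outcome), 1, 0.3),
    sex = factor(sample(c("female", "male"), length(outcome), replace = TRUE),
                 levels = c("female", "male")),
    BACS = stats::rnorm(length(outcome), 57, 12),
    BAI = pmax(0, stats::rnorm(length(outcome), 17, 13)),
    outcome = factor(outcome, levels = c("remitted", "converted", "maintained"))
  ))
}

# independent step-up BH oracle, straight from the definition
bh_brute_force <- function(p, m = length(p)) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- Inf
  for (i in seq(n, 1)) {
    rank_i <- i
    val <- p[ord[i]] * m / rank_i
    running_min <- min(running_min, val)
    adj[ord[i]] <- min(1, running_min)
  }
  adj
}
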