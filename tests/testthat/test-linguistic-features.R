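test_that("WPM follows the x0.75 rule and the dimensional mode matches AR without pauses", {
  tx100 <- make_transcript(seq(0, 39.6, by = 0.4), seq(0.3, 39.9, by = 0.4), total = 45)
  expect_equal(nrow(tx100$tokens), 100)
  expect_equal(as.numeric(compute_wpm(tx100)), 75)
  expect_equal(attr(compute_wpm(tx100), "wpm_mode"), "x0.75")

  tx48 <- make_transcript(seq(0, 18.8, by = 0.4), seq(0.3, 19.1, by = 0.4), total = 45)
  expect_equal(nrow(tx48$tokens), 48)
  expect_equal(as.numeric(compute_wpm(tx48)), 36)

  empty <- timed_transcript(data.frame(text = character(0), start_s = numeric(0),
                                       end_s = numeric(0)), total_duration_s = 45)
  expect_equal(as.numeric(compute_wpm(empty)), 0)

  # dimensional mode: wpm = 60 * ar when the transcript has no pauses
  full <- make_transcript(c(0, 1, 2), c(1, 2, 3), total = 3)
  expect_equal(as.numeric(compute_wpm(full, mode = "per_minute")),
               60 * compute_ar(full))
})

test_that("speaking duration and articulation rate follow the interval arithmetic", {
  tx <- make_transcript(c(0, 1.5), c(1, 2), total = 3)
  expect_equal(speaking_duration(tx), 1.5)

  # 30 words over 15 s of speech -> AR = 2 words/s
  tx30 <- make_transcript(seq(0, 29) * 0.6, seq(0, 29) * 0.6 + 0.5, total = 45)
  expect_equal(speaking_duration(tx30), 15)
  expect_equal(compute_ar(tx30), 2)

  one <- make_transcript(0, 0.5, total = 1)
  expect_equal(compute_ar(one), 2)

  empty <- timed_transcript(data.frame(text = character(0), start_s = numeric(0),
                                       end_s = numeric(0)), total_duration_s = 45)
  expect_equal(speaking_duration(empty), 0)
  expect_error(compute_ar(empty), "no speech")
})

test_that("pause classification uses left-closed, right-open boundaries", {
  expect_equal(classify_pause(0.29), "short")
  expect_equal(classify_pause(0.30), "medium")
  expect_equal(classify_pause(0.699), "medium")
  expect_equal(classify_pause(0.70), "long")
  expect_error(classify_pause(0), "positive")
  expect_error(classify_pause(-1), "positive")
})

test_that("interjection detection uses the tagger when given, else the lexicon", {
  toks <- c("um", "I", "sing")
  expect_equal(detect_interjections(toks), c(TRUE, FALSE, FALSE))
  expect_equal(detect_interjections(toks, lexicon = character(0)),
               rep(FALSE, 3))
  all_intj <- function(x) rep("INTJ", length(x))
  expect_equal(detect_interjections(toks, tagger = all_intj), rep(TRUE, 3))
  bad_tagger <- function(x) "INTJ"
  expect_error(detect_interjections(toks, tagger = bad_tagger), "tags")
  expect_error(detect_interjections(character(0)), "non-empty")
})

test_that("dysfluency counts short/medium pauses and interjections against word count", {
  # 20 words; gaps engineered: 2 short (0.1 s), 1 medium (0.5 s); one token "um"
  gaps <- c(0.1, 0.1, 0.5, rep(0, 16))
  starts <- cumsum(c(0, 0.3 + gaps))
  ends <- starts + 0.3
  texts <- c("um", paste0("w", 2:20))
  tx <- make_transcript(starts[1:20], ends[1:20], texts, total = 45)
  expect_equal(sum(tx$pauses$class == "short"), 2)
  expect_equal(sum(tx$pauses$class == "medium"), 1)
  expect_equal(compute_dysfluency(tx), (2 + 1 + 1) / 20)

  # only long pauses: excluded from the numerator
  gl <- c(rep(1.0, 3), rep(0, 6))
  s2 <- cumsum(c(0, 0.3 + gl))
  tx2 <- make_transcript(s2[1:10], s2[1:10] + 0.3, paste0("w", 1:10), total = 45)
  expect_equal(sum(tx2$pauses$class == "long"), 3)
  expect_equal(compute_dysfluency(tx2), 0)

  empty <- timed_transcript(data.frame(text = character(0), start_s = numeric(0),
                                       end_s = numeric(0)), total_duration_s = 45)
  expect_error(compute_dysfluency(empty), "zero words")
})

test_that("adjacent similarities match a brute-force cosine computation", {
  emb <- make_embeddings(c("a", "b", "c"),
                         rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 2)))
  expect_equal(adjacent_similarities(c("a", "a", "a"), emb), c(1, 1))

  orth <- make_embeddings(c("x", "y"), rbind(c(1, 0), c(0, 1)))
  expect_equal(adjacent_similarities(c("x", "y", "x", "y"), orth),
               rep(0, 3), tolerance = 1e-12)

  sims <- adjacent_similarities(c("a", "b", "c"), emb)
  V <- emb$vectors
  brute <- c(sum(V["a", ] * V["b", ]), sum(V["b", ] * V["c", ]))
  expect_equal(sims, brute, tolerance = 1e-9)

  expect_error(adjacent_similarities(c("a", "zzz"), emb, oov_policy = "error"), "zzz")
  expect_error(adjacent_similarities(c("a", "zzz"), emb), "at least 2")
})

test_that("sequential coherence equals the smooth-then-mean oracle", {
  emb <- make_embeddings(c("a", "b"), rbind(c(1, 0), c(1, 0)))
  # constant similarity sequence c -> sc = c (here c = 1)
  expect_equal(compute_sc(rep(c("a", "b"), 5), emb), 1)

  two <- make_embeddings(c("p", "q"), rbind(c(1, 0), c(1, 1)))
  expect_equal(compute_sc(c("p", "q"), two), sum(two$vectors["p", ] * two$vectors["q", ]))

  # 10 tokens with hand-set vectors: brute-force centered moving average then mean
  set.seed(31)
  words <- letters[1:10]
  emb10 <- make_embeddings(words, matrix(rnorm(10 * 6), 10, 6))
  sims <- adjacent_similarities(words, emb10)
  sm <- vapply(seq_along(sims), function(i) {
    mean(sims[max(1, i - 2):min(length(sims), i + 2)])
  }, numeric(1))
  expect_equal(compute_sc(words, emb10, window = 5), mean(sm), tolerance = 1e-9)
})

test_that("SC is invariant to a global rotation of the embedding table", {
  set.seed(32)
  words <- letters[1:8]
  V <- matrix(rnorm(8 * 5), 8, 5)
  emb <- make_embeddings(words, V)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  emb_rot <- embedding_table(structure(emb$vectors %*% Q,
                                       dimnames = list(words, NULL)))
  toks <- sample(words, 20, replace = TRUE)
  expect_equal(compute_sc(toks, emb), compute_sc(toks, emb_rot), tolerance = 1e-9)
})

test_that("extract_linguistic populates all four features deterministically", {
  cfg <- cohort_config(seed = 8)
  coh <- generate_cohort(cfg)
  tx <- with_seed(33, synthesize_transcript(coh[1, ], cfg))
  vocab <- synthetic_vocabulary()
  emb <- build_toy_embeddings(c(vocab$word, filled_pause_lexicon()), 16,
                              c(vocab$cluster, rep("filler", length(filled_pause_lexicon()))),
                              seed = 2)
  f <- extract_linguistic(tx, emb)
  expect_named(f, c("WPM", "AR", "Dysfluency", "SC"))
  expect_equal(f$WPM, nrow(tx$tokens) * 0.75)
  expect_gte(f$AR, 0); expect_gte(f$Dysfluency, 0)
  expect_true(f$SC >= -1 && f$SC <= 1)
  expect_identical(f, extract_linguistic(tx, emb))

  tiny <- make_transcript(c(0, 1), c(0.5, 1.5), c("music", "guitar"), total = 2)
  f2 <- extract_linguistic(tiny, emb)
  expect_equal(f2$SC, adjacent_similarities(c("music", "guitar"), emb)[1])
  one <- make_transcript(0, 0.5, "music", total = 1)
  expect_error(extract_linguistic(one, emb), "at least 2")
})

test_that("embedding tables round-trip through the plain-text format", {
  dir <- withr::local_tempdir()
  emb <- build_toy_embeddings(c("alpha", "beta", "gamma"), dim = 6, seed = 3)
  p <- file.path(dir, "emb.txt")
  write_embeddings(emb, p)
  back <- read_embeddings(p)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-8)
})
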