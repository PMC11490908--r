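test_that("slice_frames implements the half-open floor convention", {
  ft <- frame_table(matrix(seq_len(500 * 2), 500, 2), 0.010)
  s <- slice_frames(ft, 2.5, 4.0)
  expect_equal(nrow(s), 150L)             # frames 250..399, 0-based
  expect_equal(s[1L, ], ft$features[251L, ])  # 0-based 250 -> R row 251
  expect_equal(nrow(slice_frames(ft, 0, 0.010)), 1L)
  expect_warning(out <- slice_frames(ft, 10, 11), "past the end")
  expect_equal(nrow(out), 0L)
  expect_warning(tr <- slice_frames(ft, 4.99, 5.5), "truncated")
  expect_equal(nrow(tr), 1L)
  expect_error(slice_frames(ft, -1, 2), "start")
})

test_that("idf follows the smoothed formula and embeddings are seeded", {
  fz <- fit_text_featurizer(c("a b", "a"))
  expect_equal(unname(fz$idf["a"]), log(3 / 3) + 1)        # in every utterance
  expect_equal(unname(fz$idf["b"]), log(3 / 2) + 1, tolerance = 1e-12)
  fz2 <- fit_text_featurizer(c("a b", "a"))
  expect_identical(fz$embedding, fz2$embedding)
  fz3 <- fit_text_featurizer(c("a b", "a"), seed = 99L)
  expect_false(identical(fz$embedding, fz3$embedding))
  expect_error(fit_text_featurizer(character()), "empty")
})

test_that("lexical profile counts words, sentence length and diversity", {
  tr <- data.frame(start_time = c(0, 2), stop_time = c(1, 3),
                   speaker = "participant",
                   value = c("the cat", "the dog"), stringsAsFactors = FALSE)
  p <- lexical_profile(tr)
  expect_equal(unname(p["word_count"]), 4)
  expect_equal(unname(p["type_token_ratio"]), 3 / 4)
  expect_equal(unname(p["mean_sentence_length"]), 2)

  one <- data.frame(start_time = 0, stop_time = 1, speaker = "participant",
                    value = "word", stringsAsFactors = FALSE)
  expect_equal(unname(lexical_profile(one)["type_token_ratio"]), 1)

  rep10 <- data.frame(start_time = 0, stop_time = 1, speaker = "participant",
                      value = paste(rep("same", 10), collapse = " "),
                      stringsAsFactors = FALSE)
  expect_equal(unname(lexical_profile(rep10)["type_token_ratio"]), 0.1)

  no_part <- data.frame(start_time = 0, stop_time = 1, speaker = "interviewer",
                        value = "hello", stringsAsFactors = FALSE)
  expect_error(lexical_profile(no_part), "no participant")
})

test_that("alignment pads, truncates and aggregates as contracted", {
  b <- tiny_bundle()
  fz <- fit_text_featurizer(b$transcript$value)
  al <- align_session(b, fz, L = 10L)
  expect_equal(al$valid_steps, 2L)          # 2 participant utterances
  expect_true(all(al$audio_seq[3:10, ] == 0))
  expect_true(all(al$text_seq[3:10, ] == 0))
  expect_equal(dim(al$text_seq), c(10L, 301L))
  expect_equal(dim(al$audio_seq), c(10L, 74L))
  expect_equal(dim(al$video_seq), c(10L, 388L))
  ## text step carries the token count in its last column
  expect_equal(al$text_seq[1L, 301L], 5)    # "it was fine i guess"

  ## truncation keeps the earliest steps
  al1 <- align_session(b, fz, L = 1L)
  expect_equal(al1$valid_steps, 1L)
  expect_equal(al1$audio_seq[1L, ], al$audio_seq[1L, ])

  ## constant features survive averaging exactly
  bc <- b
  bc$audio <- frame_table(matrix(2.5, n_frames(b$audio), 74), 0.010)
  alc <- align_session(bc, fz, L = 5L)
  expect_true(all(abs(alc$audio_seq[seq_len(alc$valid_steps), ] - 2.5) < 1e-12))

  ## interviewer-only session errors
  b_int <- b
  b_int$transcript$speaker <- "interviewer"
  expect_error(align_session(b_int, fz, L = 5L), "no participant content")
})

test_that("alignment is label-independent", {
  b <- tiny_bundle(label = 1L)
  fz <- fit_text_featurizer(b$transcript$value)
  a1 <- align_session(b, fz, L = 6L)
  b$label <- 0L
  a0 <- align_session(b, fz, L = 6L)
  expect_identical(a1$audio_seq, a0$audio_seq)
  expect_identical(a1$video_seq, a0$video_seq)
  expect_identical(a1$text_seq, a0$text_seq)
})

test_that("non-overlapping utterances consume disjoint frame slices", {
  b <- tiny_bundle()
  part <- b$transcript[b$transcript$speaker == "participant", ]
  period <- b$audio$frame_period
  ranges <- lapply(seq_len(nrow(part)), function(i)
    seq(floor(part$start_time[i] / period), floor(part$stop_time[i] / period) - 1))
  all_idx <- unlist(ranges)
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_lte(length(all_idx), n_frames(b$audio))
})

test_that("word-level alignment yields at least as many steps as sentence level", {
  b <- tiny_bundle()
  fz <- fit_text_featurizer(b$transcript$value)
  sent <- align_session(b, fz, L = 50L)
  word <- align_session(b, fz, L = 50L, level = "word")
  expect_gte(word$valid_steps, sent$valid_steps)
  expect_equal(word$valid_steps, 5L + 5L)   # token counts of the 2 utterances
  ## each word repeats its sentence's audio slice
  expect_equal(word$audio_seq[1L, ], sent$audio_seq[1L, ])
  expect_equal(word$audio_seq[6L, ], sent$audio_seq[2L, ])
})

test_that("upsampling balances to the majority count for any input", {
  mk <- function(n0, n1) cohort_index(data.frame(
    session_id = sprintf("s%03d", seq_len(n0 + n1)),
    label = c(rep(0L, n0), rep(1L, n1))))
  up <- upsample_minority(mk(130L, 59L), seed = 4L)
  expect_equal(unname(class_counts(up)), c(130L, 130L))
  ## already balanced -> identity
  bal <- mk(50L, 50L)
  expect_identical(upsample_minority(bal, seed = 1L), bal)
  ## (3,1) -> the single minority session appears 3x
  up31 <- upsample_minority(mk(3L, 1L), seed = 2L)
  expect_equal(unname(class_counts(up31)), c(3L, 3L))
  expect_equal(sum(up31$session_id == "s004"), 3L)
  ## majority rows untouched, property over random cases
  set.seed(10)
  for (i in 1:5) {
    n0 <- sample(2:40, 1); n1 <- sample(2:40, 1)
    u <- upsample_minority(mk(n0, n1), seed = i)
    expect_equal(unname(class_counts(u)), rep(max(n0, n1), 2L))
  }
  expect_error(upsample_minority(mk(5L, 0L)), "both classes")
})

test_that("padding conservation: column sums live entirely in valid steps", {
  ch <- desk_cohort(n = 4L, seed = 13L, duration = c(20, 30))
  al <- align_cohort(ch$bundles, L = 25L)
  for (s in al$sessions) {
    v <- s$valid_steps
    expect_equal(colSums(s$audio_seq), colSums(s$audio_seq[seq_len(v), , drop = FALSE]))
    expect_equal(colSums(s$text_seq), colSums(s$text_seq[seq_len(v), , drop = FALSE]))
  }
})

test_that("modality summary features have the documented widths", {
  ch <- desk_cohort(n = 4L, seed = 17L, duration = c(20, 30))
  corpus <- unlist(lapply(ch$bundles, function(b)
    b$transcript$value[b$transcript$speaker == "participant"]))
  fz <- fit_text_featurizer(corpus)
  xa <- modality_feature_matrix(ch$bundles, "audio")
  xv <- modality_feature_matrix(ch$bundles, "video")
  xt <- modality_feature_matrix(ch$bundles, "text", fz)
  expect_equal(ncol(xa), 148L)
  expect_equal(ncol(xv), 776L)
  expect_equal(ncol(xt), length(fz$vocabulary) + 3L)
  expect_equal(nrow(xa), 4L)
})
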