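test_that("cohort shell matches the spec: counts, durations, frame periods", {
  ch <- desk_cohort(n = 10L, seed = 3L, depressed_fraction = 0.3)
  expect_equal(unname(class_counts(ch$index)), c(7L, 3L))  # round(10 * 0.3) = 3
  expect_true(all(ch$index$duration >= 30 & ch$index$duration <= 60))
  b <- ch$bundles[[1L]]
  expect_equal(b$audio$frame_period, 0.010)
  expect_equal(n_frames(b$audio), round(b$duration / 0.010))
  expect_equal(n_frames(b$video), round(b$duration * 30))
  s <- ground_truth_summary(ch$index)
  expect_equal(s$n_sessions, 10L)
  expect_equal(unname(s$class_counts), c(7L, 3L))
})

test_that("degenerate duration range pins the audio frame count exactly", {
  spec <- cohort_spec(n_sessions = 2L, duration_range = c(600, 600), seed = 1L)
  b <- generate_session(0L, spec, null_signal(), seed = 5L)
  expect_equal(n_frames(b$audio), 60000L)
})

test_that("generation is deterministic: same seed gives byte-identical cohorts", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- cohort_spec(n_sessions = 3L, depressed_fraction = 0.34,
                      duration_range = c(20, 30), seed = 11L)
  sig <- signal_model()
  generate_cohort(spec, sig, dir = dir1)
  generate_cohort(spec, sig, dir = dir2)
  f1 <- sort(list.files(dir1))
  expect_identical(f1, sort(list.files(dir2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
})

test_that("class counts follow the rounding rule for any (n, fraction)", {
  cases <- list(c(189, 59 / 189, 59), c(10, 0.3, 3), c(7, 0.5, 4),
                c(25, 0.12, 3), c(50, 0.49, 24))
  for (cs in cases) {
    spec <- cohort_spec(n_sessions = cs[1], depressed_fraction = cs[2],
                        duration_range = c(10, 20), seed = 2L)
    idx <- generate_cohort(spec, null_signal())
    expect_equal(sum(idx$label), as.integer(cs[3]),
                 label = sprintf("n=%d frac=%.3f", cs[1], cs[2]))
  }
  expect_error(generate_cohort(cohort_spec(n_sessions = 1L)), "at least 2")
})

test_that("zero signal leaves per-feature class means indistinguishable", {
  ## two 200-frame sessions per class, no shift: per-feature mean difference
  ## should sit within 4 standard errors
  spec <- cohort_spec(n_sessions = 2L, duration_range = c(2, 2), seed = 21L)
  sig <- null_signal(session_sd = 1e-12)
  a0 <- generate_session(0L, spec, sig, seed = 31L)$audio$features
  a1 <- generate_session(1L, spec, sig, seed = 32L)$audio$features
  diff <- colMeans(a1) - colMeans(a0)
  se <- sqrt(1 / nrow(a0) + 1 / nrow(a1))
  expect_true(mean(abs(diff) < 4 * se) > 0.95)
})

test_that("a large audio shift is separable by a per-frame linear oracle", {
  ## sanity ceiling: with a 3-SD shift on every audio feature, the Fisher
  ## direction (equal spherical covariance -> mean difference) classifies
  ## held-out frames with error well under 1%
  spec <- cohort_spec(n_sessions = 2L, duration_range = c(5, 5), seed = 41L)
  sig <- signal_model(audio_shift = rep(3, 74), video_shift = 0,
                      session_sd = 1e-12)
  tr0 <- generate_session(0L, spec, sig, seed = 51L)$audio$features
  tr1 <- generate_session(1L, spec, sig, seed = 52L)$audio$features
  te0 <- generate_session(0L, spec, sig, seed = 53L)$audio$features
  te1 <- generate_session(1L, spec, sig, seed = 54L)$audio$features
  w <- colMeans(tr1) - colMeans(tr0)
  thr <- sum(w * (colMeans(tr1) + colMeans(tr0)) / 2)
  err <- mean(c(te0 %*% w >= thr, te1 %*% w < thr))
  expect_lt(err, 0.01)
})

test_that("depressed participants use marker tokens more often when signalled", {
  ch <- desk_cohort(n = 16L, seed = 9L, duration = c(60, 90),
                    marker_rate = 0.8, marker_base = 0.05)
  rate_of <- function(b) {
    part <- b$transcript[b$transcript$speaker == "participant", ]
    toks <- tokenize(part$value)
    mean(vapply(toks, function(t) any(t %in% gatefusion:::marker_lexicon()),
                logical(1)))
  }
  rates <- vapply(ch$bundles, rate_of, numeric(1))
  labs <- ch$index$label
  expect_gt(mean(rates[labs == 1]), mean(rates[labs == 0]))
})

test_that("ground_truth_summary errors on dangling paths naming the session", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_sessions = 2L, duration_range = c(10, 15), seed = 5L)
  idx <- generate_cohort(spec, null_signal(), dir = dir)
  file.remove(file.path(dir, paste0(idx$session_id[2L], "_meta.csv")))
  expect_error(ground_truth_summary(idx), idx$session_id[2L])
})

test_that("materialized sessions agree with on-disk copies", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_sessions = 2L, duration_range = c(10, 15), seed = 8L)
  sig <- signal_model()
  idx_disk <- generate_cohort(spec, sig, dir = dir)
  idx_mem <- generate_cohort(spec, sig)
  b_disk <- materialize_session(idx_disk, 1L)
  b_mem <- materialize_session(idx_mem, 1L)
  expect_equal(b_disk$audio$features, b_mem$audio$features)
  expect_equal(b_disk$transcript$value, b_mem$transcript$value)
})
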