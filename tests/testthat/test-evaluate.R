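test_that("confusion counts and metrics follow their closed forms", {
  cc <- confusion_counts(c(1, 1, 0, 1, 0, 0), c(1, 0, 1, 1, 0, 0))
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 2L, fp = 1L, fn = 1L, tn = 2L))
  m <- precision_recall_f1(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.6)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(m["accuracy"]), 0.7)
  ## perfect classifier
  expect_equal(unname(precision_recall_f1(list(tp = 5, fp = 0, fn = 0, tn = 5))),
               c(1, 1, 1, 1))
  ## degenerate conventions
  expect_equal(unname(precision_recall_f1(list(tp = 0, fp = 0, fn = 3, tn = 4))),
               c(0, 0, 0, 4 / 7))
  ## all calls positive on all-negative labels
  cc2 <- confusion_counts(rep(1, 5), rep(0, 5))
  expect_equal(cc2$tp, 0L)
  expect_equal(cc2$fp, 5L)
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(8)
  for (i in 1:200) {
    counts <- as.list(rmultinom(1, sample(1:200, 1), rep(0.25, 4))[, 1])
    names(counts) <- c("tp", "fp", "fn", "tn")
    m <- precision_recall_f1(counts)
    n <- counts$tp + counts$fp + counts$fn + counts$tn
    expect_equal(unname(m["accuracy"]), (counts$tp + counts$tn) / n)
    if (m["precision"] > 0 && m["recall"] > 0)
      expect_equal(unname(m["f1"]),
                   2 / (1 / m[["precision"]] + 1 / m[["recall"]]))
    expect_true(all(m >= 0 & m <= 1))
    ## swapping the positive class mirrors precision/recall
    sw <- precision_recall_f1(list(tp = counts$tn, fp = counts$fn,
                                   fn = counts$fp, tn = counts$tp))
    neg_prec <- if (counts$tn + counts$fn > 0) counts$tn / (counts$tn + counts$fn) else 0
    expect_equal(unname(sw["precision"]), neg_prec)
  }
})

test_that("stratified splits are disjoint, exhaustive and seeded", {
  labels <- rep(c(0L, 1L), c(26L, 10L))
  sp <- split_sessions(labels, test_frac = 0.2, seed = 3L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_equal(sum(labels[sp$test] == 1L), 2L)   # round(10 * 0.2)
  expect_equal(sum(labels[sp$test] == 0L), 5L)   # round(26 * 0.2)
  expect_identical(sp, split_sessions(labels, test_frac = 0.2, seed = 3L))
})

test_that("evaluation guards train/test hygiene", {
  calls <- c(1L, 0L, 1L)
  labels <- c(1L, 0L, 0L)
  expect_error(
    evaluate_predictions(calls, labels, eval_ids = c("a", "b", "c"),
                         train_ids = c("c", "d")),
    "overlap")
  expect_warning(
    rep <- evaluate_predictions(calls, labels, eval_ids = c("a", "b", "c"),
                                train_ids = c("c", "d"),
                                allow_train_eval = TRUE),
    "flagged")
  expect_true(rep$on_train)
  expect_error(evaluate_predictions(integer(), integer()), "empty")
})

test_that("comparison tables are sorted, deduplicated and split-consistent", {
  r1 <- evaluate_predictions(c(1, 0), c(1, 0), model = "b", modality = "audio",
                             split = "s1")
  r2 <- evaluate_predictions(c(1, 0), c(1, 1), model = "a", modality = "text",
                             split = "s1")
  r3 <- evaluate_predictions(c(1, 0), c(1, 1), model = "c", modality = "all",
                             split = "s2")
  tbl <- compare_models(list(r1, r2))
  expect_equal(tbl$model, c("a", "b"))
  expect_error(compare_models(list(r1, r3)), "mix")
  expect_error(compare_models(list(r1, r1)), "duplicate")
  empty <- compare_models(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("model", "modality", "f1") %in% names(empty)))
  ## report generation is pure
  expect_identical(evaluate_predictions(c(1, 0), c(1, 0), model = "m"),
                   evaluate_predictions(c(1, 0), c(1, 0), model = "m"))
})

test_that("permutation null is seeded and centres near the chance F1", {
  set.seed(9)
  calls <- rbinom(60, 1, 0.5)
  labels <- rbinom(60, 1, 0.3)
  n1 <- permutation_null_f1(calls, labels, n_perm = 100L, seed = 2L)
  n2 <- permutation_null_f1(calls, labels, n_perm = 100L, seed = 2L)
  expect_identical(n1$f1, n2$f1)
  expect_gt(n1$sd, 0)
  ## analytic chance F1 for independent calls/labels:
  ## P = prevalence, R = call rate; E[f1] approx 2PR'/(P'+R') with
  ## P' = prevalence, R' = call rate: check the null mean is in a wide band
  p_call <- mean(calls); p_lab <- mean(labels)
  approx_f1 <- 2 * p_call * p_lab / (p_call + p_lab)
  expect_lt(abs(n1$mean - approx_f1), 0.15)
})
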