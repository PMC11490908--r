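## Metrics and reporting. Positive class = depressed (label 1) throughout.

#' Confusion counts of binary calls against labels
#'
#' @param calls 0/1 predicted calls.
#' @param labels 0/1 true labels (1 = depressed = positive class).
#' @return An object of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(calls, labels) {
  if (length(calls) != length(labels))
    stopf("calls (%d) and labels (%d) differ in length", length(calls),
          length(labels))
  calls <- as.integer(calls); labels <- as.integer(labels)
  stopifnot(all(calls %in% 0:1), all(labels %in% 0:1))
  structure(list(tp = sum(calls == 1L & labels == 1L),
                 fp = sum(calls == 1L & labels == 0L),
                 fn = sum(calls == 0L & labels == 1L),
                 tn = sum(calls == 0L & labels == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' Degenerate denominators follow the zero convention: precision is 0 when no
#' positive call was made, recall is 0 when no positive label exists, and F1
#' is 0 when precision + recall = 0.
#'
#' @param c a `confusion_counts` (or list with `tp`, `fp`, `fn`, `tn`).
#' @return Named numeric vector `c(precision, recall, f1, accuracy)`.
#' @export
precision_recall_f1 <- function(c) {
  total <- c$tp + c$fp + c$fn + c$tn
  if (total < 1L) stopf("empty confusion table")
  precision <- if (c$tp + c$fp > 0L) c$tp / (c$tp + c$fp) else 0
  recall <- if (c$tp + c$fn > 0L) c$tp / (c$tp + c$fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1,
    accuracy = (c$tp + c$tn) / total)
}

#' Stratified train/test split
#'
#' Splits session indices 80/20 (by default) within each class, seeded.
#'
#' @param labels 0/1 labels.
#' @param test_frac held-out fraction (default 0.2).
#' @param seed integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
split_sessions <- function(labels, test_frac = 0.2, seed = 1L) {
  labels <- as.integer(labels)
  with_seed(seed, {
    test <- integer()
    for (cls in unique(labels)) {
      ii <- which(labels == cls)
      n_test <- max(1L, round(length(ii) * test_frac))
      test <- c(test, ii[sample.int(length(ii), n_test)])
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' Evaluate a model's calls on a held-out set
#'
#' Computes the confusion counts and metrics of predicted calls against
#' labels and packages them as one report row. Evaluating sessions that were
#' in the training set is a hard error when ids are disjointly declared, and
#' sets a warning flag when the caller evaluates on its own training ids.
#'
#' @param calls 0/1 predicted calls on the evaluation sessions.
#' @param labels 0/1 true labels of the evaluation sessions.
#' @param model model name for the report.
#' @param modality modality combination string, e.g. `"audio+text"`.
#' @param split free-text split description (recorded in the report).
#' @param seed seed(s) used, recorded in the report.
#' @param eval_ids,train_ids optional session ids; overlap raises an error
#'   unless `allow_train_eval = TRUE`, which instead flags the row.
#' @param allow_train_eval set TRUE to evaluate on training sessions (the row
#'   is flagged `on_train`).
#' @return One-row data.frame of class `eval_report`.
#' @export
evaluate_predictions <- function(calls, labels, model = "model", modality = "all",
                                 split = "unspecified", seed = NA_integer_,
                                 eval_ids = NULL, train_ids = NULL,
                                 allow_train_eval = FALSE) {
  if (!length(labels)) stopf("empty evaluation set")
  on_train <- FALSE
  if (!is.null(eval_ids) && !is.null(train_ids)) {
    overlap <- intersect(eval_ids, train_ids)
    if (length(overlap)) {
      if (!allow_train_eval)
        stopf("evaluation sessions overlap the training split: %s",
              paste(utils::head(overlap, 5L), collapse = ", "))
      on_train <- TRUE
      warnf("evaluating on %d training session(s); report row flagged", length(overlap))
    }
  }
  cc <- confusion_counts(calls, labels)
  met <- precision_recall_f1(cc)
  out <- data.frame(model = model, modality = modality,
                    precision = met[["precision"]], recall = met[["recall"]],
                    f1 = met[["f1"]], accuracy = met[["accuracy"]],
                    tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
                    n = length(labels), split = split, seed = seed,
                    on_train = on_train, stringsAsFactors = FALSE)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Evaluate a fitted model on held-out sessions
#'
#' Dispatches `predict()` on the model, then delegates to
#' [evaluate_predictions()].
#'
#' @param object a fitted model with a `predict(object, sessions_or_features)`
#'   method returning a `call` column (e.g. `fusion_fit`, `cnn_model`,
#'   `modality_classifier`, `stacked_fusion`).
#' @param newdata held-out input in the form the model's `predict` expects.
#' @param labels 0/1 labels of `newdata`.
#' @param ... passed to [evaluate_predictions()] (including the report's
#'   `model` and `modality` names).
#' @return One-row `eval_report`.
#' @export
evaluate_model <- function(object, newdata, labels, ...) {
  pred <- stats::predict(object, newdata)
  evaluate_predictions(pred$call, labels, ...)
}

#' Combine report rows into a comparison table
#'
#' @param reports list of `eval_report` rows sharing one split.
#' @return An `eval_report` data.frame, one row per (model, modality), sorted
#'   by model then modality; duplicate (model, modality) pairs or mixed splits
#'   raise errors.
#' @export
compare_models <- function(reports) {
  if (!length(reports)) {
    out <- data.frame(model = character(), modality = character(),
                      precision = numeric(), recall = numeric(), f1 = numeric(),
                      accuracy = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("eval_report", "data.frame")
    return(out)
  }
  df <- do.call(rbind, lapply(reports, as.data.frame))
  if (length(unique(df$split)) > 1L)
    stopf("reports mix different splits: %s",
          paste(unique(df$split), collapse = " vs "))
  key <- paste(df$model, df$modality)
  if (anyDuplicated(key))
    stopf("duplicate (model, modality) row: %s", key[duplicated(key)][1L])
  df <- df[order(df$model, df$modality), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("eval_report", "data.frame")
  df
}

#' @export
print.eval_report <- function(x, digits = 3L, ...) {
  df <- as.data.frame(x)
  for (col in intersect(c("precision", "recall", "f1", "accuracy"), names(df)))
    df[[col]] <- round(df[[col]], digits)
  print.data.frame(df[, intersect(c("model", "modality", "precision", "recall",
                                    "f1", "accuracy", "n", "split"), names(df))],
                   row.names = FALSE)
  invisible(x)
}

#' Permutation null distribution of the F1 score
#'
#' The reference band for "no better than chance": the F1 of the observed
#' calls against label permutations of the evaluation set.
#'
#' @param calls 0/1 predicted calls.
#' @param labels 0/1 true labels.
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed.
#' @return List with `mean`, `sd` and the permuted `f1` values.
#' @export
permutation_null_f1 <- function(calls, labels, n_perm = 200L, seed = 1L) {
  f1s <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    precision_recall_f1(confusion_counts(calls, sample(labels)))[["f1"]]
  }, numeric(1L)))
  list(mean = mean(f1s), sd = stats::sd(f1s), f1 = f1s)
}
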