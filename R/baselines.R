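## Classical per-modality classifiers, recurrent variants and stacked late
## fusion.
##
## First stage: an SVM or random forest per modality on session-level summary
## features, producing out-of-fold scores by 5-fold cross-fitting so the
## second stage never sees a score from a model trained on that session.
## Second stage: an SVM on the concatenated first-stage scores (late fusion).

#' Train a per-modality classical classifier
#'
#' Fits an SVM (`kind = "max-margin"`, radial kernel) or a random forest on a
#' session-by-feature matrix and returns, alongside the full-data fit,
#' out-of-fold scores from seeded 5-fold cross-fitting: the score of each
#' session comes from a model that never saw it, so downstream stacking is
#' leakage-free.
#'
#' @param x numeric feature matrix, one row per session.
#' @param y 0/1 labels.
#' @param kind `"max-margin"` (SVM) or `"random-forest"`.
#' @param seed integer seed.
#' @param folds number of cross-fitting folds (default 5).
#' @return An object of class `modality_classifier` with elements `fit`,
#'   `oof_scores` (in [0, 1]), `kind`, `folds` (fold assignment).
#' @export
train_modality_classifier <- function(x, y, kind = c("max-margin", "random-forest"),
                                      seed = 1L, folds = 5L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("training set contains a single class")
  if (min(table(y)) < 2L) stopf("need at least 2 sessions per class")
  n <- nrow(x)
  folds <- min(folds, min(table(y)))
  ## drop constant columns (zero variance breaks SVM scaling)
  keep <- which(apply(x, 2L, stats::sd) > 0)
  if (!length(keep)) stopf("all features are constant")
  fit_one <- function(xtr, ytr, s) {
    ## columns constant within this training subset carry no information and
    ## break the SVM's internal scaling; drop them per fit
    cols <- which(apply(xtr, 2L, stats::sd) > 0)
    fit <- with_seed(s, {
      if (kind == "max-margin") {
        e1071::svm(xtr[, cols, drop = FALSE], factor(ytr, levels = c(0L, 1L)),
                   kernel = "radial", scale = TRUE)
      } else {
        randomForest::randomForest(xtr[, cols, drop = FALSE],
                                   factor(ytr, levels = c(0L, 1L)),
                                   ntree = 200L)
      }
    })
    list(fit = fit, cols = cols)
  }
  score_one <- function(f, xte) {
    xte <- xte[, f$cols, drop = FALSE]
    if (kind == "max-margin") {
      dv <- attr(stats::predict(f$fit, xte, decision.values = TRUE),
                 "decision.values")
      ## decision value sign depends on which class e1071 saw first
      sgn <- if (grepl("^0", colnames(dv)[1L])) -1 else 1
      as.numeric(sigmoid(sgn * dv[, 1L]))
    } else {
      as.numeric(stats::predict(f$fit, xte, type = "prob")[, "1"])
    }
  }
  ## stratified fold assignment
  assign_folds <- with_seed(seed, {
    fa <- integer(n)
    for (cls in c(0L, 1L)) {
      ii <- which(y == cls)
      fa[ii] <- sample(rep_len(seq_len(folds), length(ii)))
    }
    fa
  })
  oof <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    tr <- which(assign_folds != k)
    te <- which(assign_folds == k)
    if (length(unique(y[tr])) < 2L) stopf("fold %d left a single-class training set", k)
    f <- fit_one(x[tr, keep, drop = FALSE], y[tr], derive_seed(seed, k))
    oof[te] <- score_one(f, x[te, keep, drop = FALSE])
  }
  full_fit <- fit_one(x[, keep, drop = FALSE], y, seed)
  structure(list(fit = full_fit, kind = kind, keep = keep,
                 oof_scores = oof, folds = assign_folds,
                 score_fun = score_one),
            class = "modality_classifier")
}

#' @export
print.modality_classifier <- function(x, ...) {
  cat(sprintf("<modality_classifier> %s, %d features, %d-fold out-of-fold scores\n",
              x$kind, length(x$keep), max(x$folds)))
  invisible(x)
}

#' @export
predict.modality_classifier <- function(object, newdata, threshold = 0.5, ...) {
  newdata <- as.matrix(newdata)[, object$keep, drop = FALSE]
  prob <- object$score_fun(object$fit, newdata)
  data.frame(prob = prob, call = as.integer(prob >= threshold))
}

#' Second-stage late fusion by stacking
#'
#' Trains the second-stage SVM on the concatenation of first-stage scores
#' (one column per model x modality member, fixed order). Feed it out-of-fold
#' scores so the stack never sees in-fold predictions.
#'
#' @param scores numeric matrix, sessions x members; column order is the
#'   fusion order and must be reused at prediction time.
#' @param labels 0/1 session labels.
#' @param seed integer seed.
#' @return An object of class `stacked_fusion`.
#' @export
late_fuse_stacking <- function(scores, labels, seed = 1L) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) {
    bad <- which(rowSums(is.na(scores)) > 0L)
    nm <- rownames(scores)[bad] %||% as.character(bad)
    stopf("missing first-stage score(s) for session(s): %s",
          paste(nm, collapse = ", "))
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("stacking needs both classes")
  fit <- with_seed(seed, e1071::svm(scores, factor(labels, levels = c(0L, 1L)),
                                    kernel = "linear", scale = FALSE))
  structure(list(fit = fit, n_members = ncol(scores),
                 members = colnames(scores)),
            class = "stacked_fusion")
}

#' @export
print.stacked_fusion <- function(x, ...) {
  cat(sprintf("<stacked_fusion> second-stage SVM over %d first-stage score(s)\n",
              x$n_members))
  invisible(x)
}

#' @export
predict.stacked_fusion <- function(object, newdata, threshold = 0.5, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_members)
    stopf("expected %d score column(s), got %d", object$n_members, ncol(newdata))
  dv <- attr(stats::predict(object$fit, newdata, decision.values = TRUE),
             "decision.values")
  sgn <- if (grepl("^0", colnames(dv)[1L])) -1 else 1
  prob <- as.numeric(sigmoid(sgn * dv[, 1L]))
  data.frame(prob = prob, call = as.integer(prob >= threshold))
}

#' Combine per-model scores for the same sessions
#'
#' Default combination is the unweighted mean of member probabilities;
#' `method = "stack"` feeds the members into [late_fuse_stacking()] instead
#' (requires `labels`).
#'
#' @param score_list named list of numeric score vectors, all aligned to the
#'   same sessions (names checked when present).
#' @param method `"mean"` or `"stack"`.
#' @param labels 0/1 labels, required for `"stack"`.
#' @param seed integer seed for `"stack"`.
#' @return For `"mean"`, a numeric vector; for `"stack"`, a `stacked_fusion`.
#' @export
ensemble_scores <- function(score_list, method = c("mean", "stack"),
                            labels = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(score_list) >= 1L)
  lens <- vapply(score_list, length, integer(1L))
  if (length(unique(lens)) != 1L) stopf("members score different session counts")
  named <- Filter(Negate(is.null), lapply(score_list, names))
  if (length(named) > 1L && !all(vapply(named[-1L], identical, logical(1L),
                                        named[[1L]])))
    stopf("member score session ids do not match")
  m <- do.call(cbind, score_list)
  if (method == "mean") {
    rowMeans(m)
  } else {
    if (is.null(labels)) stopf("stacking combination requires labels")
    late_fuse_stacking(m, labels, seed = seed)
  }
}

#' Train an LSTM / BiLSTM sequence variant
#'
#' The recurrent comparison models: selected modalities are (optionally)
#' gated, projected to the common fusion width, concatenated along time and
#' fed to an LSTM or BiLSTM head. `gating = "none"` omits the gating blocks;
#' `"sentence"` gates the per-utterance steps; `"word"` re-aligns the bundles
#' at word level (each token its own step, the utterance's audio/video slice
#' repeated per word) before gating.
#'
#' @param bundles list of `session_bundle`s.
#' @param featurizer fitted `text_featurizer`.
#' @param L aligned sequence length.
#' @param kind `"lstm"` or `"bilstm"`.
#' @param gating `"none"`, `"sentence"` or `"word"`.
#' @param modalities streams to include.
#' @param n_gating gating blocks per gated stream (default 1).
#' @param units recurrent units (default 128).
#' @param epochs,batch_size,lr,seed as in [train_fusion()].
#' @return A `fusion_fit` whose spec records the variant.
#' @export
train_sequence_variant <- function(bundles, featurizer, L,
                                   kind = c("lstm", "bilstm"),
                                   gating = c("none", "sentence", "word"),
                                   modalities = c("audio", "video", "text"),
                                   n_gating = 1L, units = 128L,
                                   epochs = 20L, batch_size = 8L, lr = 1e-3,
                                   seed = 1L) {
  kind <- match.arg(kind)
  gating <- match.arg(gating)
  level <- if (gating == "word") "word" else "sentence"
  sessions <- lapply(bundles, align_session, featurizer = featurizer, L = L,
                     level = level)
  spec <- network_spec(L = L, modalities = modalities,
                       n_gating = if (gating == "none") 0L else n_gating,
                       recurrent = kind, units = units, seed = seed)
  net <- fusion_network(spec)
  net$gating_level <- gating
  fit <- train_fusion(net, sessions, epochs = epochs, batch_size = batch_size,
                      lr = lr, seed = seed)
  fit$gating_level <- gating
  fit$alignment_level <- level
  fit
}
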