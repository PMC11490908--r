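## Sentence-level alignment and featurization.
##
## Each participant utterance becomes one time step: its audio/video step is
## the per-feature mean over the frames inside the utterance's timestamp
## window, and its text step is the mean of the token embeddings (300-d)
## concatenated with the token count, giving 301 dimensions. Sequences are
## padded with zero rows (or truncated, keeping the earliest steps) to a fixed
## length L so the three modalities share one time index.

TEXT_EMBED_D <- 300L
TEXT_D <- 301L

#' Slice a frame table by a time window
#'
#' Returns the frames whose 0-based index lies in
#' `[floor(start/period), floor(stop/period))` — a half-open window. A window
#' reaching past the end of the table is truncated with a warning; a window
#' entirely past the end yields a 0-row matrix.
#'
#' @param frames a `frame_table`.
#' @param start,stop window bounds in seconds, `0 <= start < stop`.
#' @return Numeric matrix of the selected rows.
#' @export
slice_frames <- function(frames, start, stop) {
  if (start < 0 || stop <= start) stopf("need 0 <= start < stop")
  period <- frames$frame_period
  lo <- floor(start / period)       # first frame, 0-based
  hi <- floor(stop / period)        # one past the last frame, 0-based
  n <- n_frames(frames)
  if (lo >= n) {
    warnf("frame window [%.3f, %.3f) lies past the end of the table (%d frames)",
          start, stop, n)
    return(frames$features[0L, , drop = FALSE])
  }
  if (hi > n) {
    warnf("frame window [%.3f, %.3f) truncated to %d available frame(s)",
          start, stop, n - lo)
    hi <- n
  }
  frames$features[(lo + 1L):hi, , drop = FALSE]
}

.tokenize <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9 ]", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

#' Tokenize utterance text
#'
#' Lowercases, strips punctuation and splits on whitespace.
#'
#' @param texts character vector of utterances.
#' @return List of character token vectors, one per utterance.
#' @export
tokenize <- function(texts) lapply(texts, .tokenize)

#' Fit a text featurizer on a corpus of utterances
#'
#' Builds the vocabulary, smoothed inverse document frequencies
#' `idf(t) = ln((1 + N) / (1 + df_t)) + 1` (N = number of utterances), and a
#' deterministically seeded random embedding table (300-d per token). The
#' embedding table stands in for any pretrained sentence encoder; swap in
#' another via the `embeddings` argument.
#'
#' @param corpus character vector of participant utterances.
#' @param embedding_dim embedding width (default 300).
#' @param seed integer seed for the embedding table.
#' @param embeddings optional matrix (vocabulary x embedding_dim) overriding
#'   the random table; rows matched by vocabulary order.
#' @return An object of class `text_featurizer` with elements `vocabulary`
#'   (token -> column index), `idf`, `embedding`, `n_docs`.
#' @export
fit_text_featurizer <- function(corpus, embedding_dim = TEXT_EMBED_D, seed = 1L,
                                embeddings = NULL) {
  corpus <- corpus[nzchar(trimws(corpus))]
  if (!length(corpus)) stopf("cannot fit a text featurizer on an empty corpus")
  tok <- tokenize(corpus)
  vocab <- sort(unique(unlist(tok)))
  df <- vapply(vocab, function(t) sum(vapply(tok, function(u) t %in% u, logical(1L))),
               numeric(1L))
  n_docs <- length(corpus)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  names(idf) <- vocab
  emb <- if (is.null(embeddings)) {
    with_seed(seed, matrix(stats::rnorm(length(vocab) * embedding_dim,
                                        sd = 1 / sqrt(embedding_dim)),
                           length(vocab), embedding_dim))
  } else {
    stopifnot(nrow(embeddings) == length(vocab), ncol(embeddings) == embedding_dim)
    as.matrix(embeddings)
  }
  rownames(emb) <- vocab
  structure(list(vocabulary = stats::setNames(seq_along(vocab), vocab),
                 idf = idf, embedding = emb, embedding_dim = embedding_dim,
                 n_docs = n_docs, seed = seed),
            class = "text_featurizer")
}

#' @export
print.text_featurizer <- function(x, ...) {
  cat(sprintf("<text_featurizer> %d tokens, %d-d embeddings, fitted on %d utterances\n",
              length(x$vocabulary), x$embedding_dim, x$n_docs))
  invisible(x)
}

## One 301-d text step: mean embedding of the utterance's tokens (zeros when
## no token is in-vocabulary) followed by the token count.
text_step <- function(featurizer, text) {
  toks <- .tokenize(text)
  known <- toks[toks %in% names(featurizer$vocabulary)]
  emb <- if (length(known)) {
    colMeans(featurizer$embedding[known, , drop = FALSE])
  } else {
    numeric(featurizer$embedding_dim)
  }
  c(emb, length(toks))
}

#' Session-level TF-IDF vector
#'
#' Term counts over the given utterances weighted by the featurizer's idf and
#' L2-normalized; the text input of the classical per-modality classifiers.
#'
#' @param featurizer a fitted `text_featurizer`.
#' @param texts character vector of utterances (one session's participant
#'   speech).
#' @return Numeric vector over the featurizer's vocabulary.
#' @export
tfidf_vector <- function(featurizer, texts) {
  toks <- unlist(tokenize(texts))
  v <- numeric(length(featurizer$vocabulary))
  names(v) <- names(featurizer$vocabulary)
  tab <- table(toks[toks %in% names(v)])
  v[names(tab)] <- as.numeric(tab) * featurizer$idf[names(tab)]
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Lexical profile of a participant transcript
#'
#' Word count, mean sentence (utterance) length in tokens, and type-token
#' ratio (distinct / total tokens) over the participant utterances.
#'
#' @param transcript transcript data.frame (see [read_transcript()]).
#' @return Named numeric vector `c(word_count, mean_sentence_length,
#'   type_token_ratio)`.
#' @export
lexical_profile <- function(transcript) {
  part <- transcript[transcript$speaker == "participant", , drop = FALSE]
  if (!nrow(part)) stopf("no participant content")
  toks <- tokenize(part$value)
  counts <- lengths(toks)
  total <- sum(counts)
  if (total == 0L) stopf("participant transcript contains no tokens")
  c(word_count = total,
    mean_sentence_length = mean(counts),
    type_token_ratio = length(unique(unlist(toks))) / total)
}

#' Align a session's modalities at the sentence level
#'
#' One time step per participant utterance (interviewer turns dropped), in
#' transcript order. Per step: the audio and video vectors are the per-feature
#' means over the utterance's frame slices (zeros if the slice is empty) and
#' the text vector is the 300-d mean token embedding plus the token count.
#' Sequences are zero-padded, or truncated keeping the earliest steps, to
#' length `L`.
#'
#' @param bundle a `session_bundle`.
#' @param featurizer a fitted `text_featurizer`.
#' @param L fixed sequence length (default 1700).
#' @param agg frame aggregation within an utterance: `"mean"` (default),
#'   `"max"` or `"sd"`.
#' @param level `"sentence"` (default) or `"word"`. At word level every token
#'   is its own step (text step = that token's embedding plus a count of 1)
#'   and the utterance's audio/video slice mean is repeated for each of its
#'   words.
#' @return An `aligned_session`: list with `text_seq` (L x 301), `audio_seq`
#'   (L x 74), `video_seq` (L x 388), `valid_steps`, `label`, `L`.
#' @export
align_session <- function(bundle, featurizer, L = 1700L,
                          agg = c("mean", "max", "sd"),
                          level = c("sentence", "word")) {
  agg <- match.arg(agg)
  level <- match.arg(level)
  part <- bundle$transcript[bundle$transcript$speaker == "participant", ,
                            drop = FALSE]
  if (!nrow(part)) stopf("no participant content")
  agg_fun <- switch(agg, mean = colMeans,
                    max = function(m) apply(m, 2L, max),
                    sd = col_sds)
  step_of <- function(frames, start, stop) {
    sl <- suppressWarnings(slice_frames(frames, start, stop))
    if (nrow(sl) == 0L) numeric(ncol(sl)) else agg_fun(sl)
  }
  audio_steps <- list(); video_steps <- list(); text_steps <- list()
  for (i in seq_len(nrow(part))) {
    a <- step_of(bundle$audio, part$start_time[i], part$stop_time[i])
    v <- step_of(bundle$video, part$start_time[i], part$stop_time[i])
    if (level == "sentence") {
      audio_steps[[length(audio_steps) + 1L]] <- a
      video_steps[[length(video_steps) + 1L]] <- v
      text_steps[[length(text_steps) + 1L]] <- text_step(featurizer, part$value[i])
    } else {
      toks <- .tokenize(part$value[i])
      if (!length(toks)) next
      for (tk in toks) {
        audio_steps[[length(audio_steps) + 1L]] <- a
        video_steps[[length(video_steps) + 1L]] <- v
        e <- if (tk %in% names(featurizer$vocabulary)) {
          featurizer$embedding[tk, ]
        } else numeric(featurizer$embedding_dim)
        text_steps[[length(text_steps) + 1L]] <- c(e, 1)
      }
    }
  }
  n_steps <- length(audio_steps)
  if (!n_steps) stopf("no participant content")
  valid <- min(n_steps, L)
  pad <- function(steps, d) {
    m <- matrix(0, L, d)
    if (valid > 0L)
      m[seq_len(valid), ] <- do.call(rbind, steps[seq_len(valid)])
    m
  }
  structure(list(text_seq = pad(text_steps, TEXT_D),
                 audio_seq = pad(audio_steps, AUDIO_D),
                 video_seq = pad(video_steps, VIDEO_D),
                 valid_steps = valid, label = bundle$label, L = as.integer(L),
                 session_id = bundle$session_id, level = level),
            class = "aligned_session")
}

#' @export
print.aligned_session <- function(x, ...) {
  cat(sprintf("<aligned_session> %s: %d/%d valid steps (%s level), label %d\n",
              x$session_id, x$valid_steps, x$L, x$level, x$label))
  invisible(x)
}

#' Align every session of a cohort
#'
#' Fits a text featurizer on all participant utterances of the cohort (unless
#' one is supplied) and aligns each session. Alignment is label-independent:
#' labels are only copied through.
#'
#' @param bundles list of `session_bundle`s.
#' @param L fixed sequence length.
#' @param featurizer optional pre-fitted `text_featurizer`.
#' @param ... passed to [align_session()].
#' @return List with `sessions` (list of `aligned_session`), `featurizer`,
#'   `labels`.
#' @export
align_cohort <- function(bundles, L = 1700L, featurizer = NULL, ...) {
  if (is.null(featurizer)) {
    corpus <- unlist(lapply(bundles, function(b) {
      b$transcript$value[b$transcript$speaker == "participant"]
    }))
    featurizer <- fit_text_featurizer(corpus)
  }
  sessions <- lapply(bundles, align_session, featurizer = featurizer, L = L, ...)
  list(sessions = sessions, featurizer = featurizer,
       labels = vapply(sessions, `[[`, integer(1L), "label"))
}

#' Balance a cohort index by upsampling the minority class
#'
#' Duplicates minority-class entries (sampling with replacement, seeded) until
#' both class counts equal the original majority count; majority entries are
#' untouched. Run this on the training split only, after splitting, so
#' duplicated sessions never straddle a train/test boundary.
#'
#' @param index a `cohort_index`.
#' @param seed integer seed.
#' @return A `cohort_index` with equal class counts; duplicated rows keep
#'   their session ids.
#' @export
upsample_minority <- function(index, seed = 1L) {
  cc <- class_counts(index)
  if (any(cc == 0L)) stopf("both classes must be present to upsample")
  if (cc[1L] == cc[2L]) return(index)
  minority <- if (cc[["depressed"]] < cc[["non_depressed"]]) 1L else 0L
  need <- abs(cc[1L] - cc[2L])
  pool <- which(index$label == minority)
  extra <- with_seed(seed, pool[sample.int(length(pool), need, replace = TRUE)])
  out <- rbind(as.data.frame(index), as.data.frame(index)[extra, , drop = FALSE])
  rownames(out) <- NULL
  out <- structure(out, class = c("cohort_index", "data.frame"))
  attr(out, "spec") <- attr(index, "spec")
  attr(out, "signal") <- attr(index, "signal")
  attr(out, "upsampled") <- TRUE
  out
}

#' Session-level summary features for the classical classifiers
#'
#' Text: the TF-IDF vector plus the lexical profile (word count, mean sentence
#' length, type-token ratio). Audio/video: per-feature session-level mean and
#' standard deviation over all frames (74 -> 148, 388 -> 776 dimensions).
#'
#' @param bundle a `session_bundle`.
#' @param modality `"text"`, `"audio"` or `"video"`.
#' @param featurizer fitted `text_featurizer` (text modality only).
#' @return Named numeric feature vector.
#' @export
modality_features <- function(bundle, modality = c("text", "audio", "video"),
                              featurizer = NULL) {
  modality <- match.arg(modality)
  if (modality == "text") {
    if (is.null(featurizer)) stopf("text features require a fitted featurizer")
    part <- bundle$transcript$value[bundle$transcript$speaker == "participant"]
    c(tfidf_vector(featurizer, part), lexical_profile(bundle$transcript))
  } else {
    m <- if (modality == "audio") bundle$audio$features else bundle$video$features
    mu <- colMeans(m)
    sd_ <- col_sds(m)
    stats::setNames(c(mu, sd_),
                    c(paste0(modality, "_mean_", seq_along(mu)),
                      paste0(modality, "_sd_", seq_along(sd_))))
  }
}

#' Feature matrix for one modality over a cohort
#'
#' @param bundles list of `session_bundle`s.
#' @param modality `"text"`, `"audio"` or `"video"`.
#' @param featurizer fitted `text_featurizer` (required for text).
#' @return Numeric matrix, one row per session.
#' @export
modality_feature_matrix <- function(bundles, modality, featurizer = NULL) {
  rows <- lapply(bundles, modality_features, modality = modality,
                 featurizer = featurizer)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(bundles, `[[`, character(1L), "session_id")
  m
}
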