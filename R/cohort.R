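## Synthetic cohort generator.
##
## Emulates the statistical shell of a DAIC-WOZ-style corpus — 189 sessions,
## 59 depressed / 130 non-depressed, 7-33 minute interviews, 74 audio features
## per 10 ms frame, 388 video features per video frame, alternating
## interviewer/participant utterances — with controllable per-modality class
## signal so every downstream stage is testable without the licensed corpus.

#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the corpus shell: 189 sessions with a 59/189 depressed
#' fraction, 7-33 min durations, audio frames every 10 ms, video at 30 Hz and
#' roughly 8 utterances per minute alternating between interviewer and
#' participant.
#'
#' @param n_sessions number of sessions (default 189).
#' @param depressed_fraction fraction of depressed sessions (default 59/189).
#' @param duration_range session duration bounds in seconds (default 420-1980).
#' @param audio_frame_period audio frame spacing in seconds (default 0.010).
#' @param video_frame_period video frame spacing in seconds (default 1/30).
#' @param utterance_rate utterances per minute, both speakers (default 8).
#' @param seed integer seed driving all generator randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sessions = 189L, depressed_fraction = 59 / 189,
                        duration_range = c(420, 1980),
                        audio_frame_period = 0.010,
                        video_frame_period = 1 / 30,
                        utterance_rate = 8, seed = 1L) {
  if (depressed_fraction <= 0 || depressed_fraction >= 1)
    stopf("depressed_fraction must be in (0, 1)")
  if (length(duration_range) != 2L || duration_range[1L] > duration_range[2L])
    stopf("duration_range must be increasing (or equal) bounds in seconds")
  structure(list(n_sessions = as.integer(n_sessions),
                 depressed_fraction = depressed_fraction,
                 duration_range = as.numeric(duration_range),
                 audio_frame_period = audio_frame_period,
                 video_frame_period = video_frame_period,
                 utterance_rate = utterance_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d sessions, depressed fraction %.4f, ",
                     "durations %.0f-%.0f s, seed %d\n"),
              x$n_sessions, x$depressed_fraction, x$duration_range[1L],
              x$duration_range[2L], x$seed))
  invisible(x)
}

## Tokens carrying the depressed-class text signal; a small anhedonia/fatigue
## lexicon so TF-IDF features can pick the classes apart mechanically.
marker_lexicon <- function() {
  c("tired", "hopeless", "empty", "worthless", "alone", "numb",
    "exhausted", "guilty", "drained", "down")
}

## Neutral conversational filler both classes draw from.
base_lexicon <- function() {
  c("i", "you", "we", "they", "it", "was", "is", "been", "have", "had",
    "think", "know", "feel", "felt", "said", "went", "work", "home",
    "family", "friends", "time", "day", "week", "night", "sleep", "really",
    "maybe", "about", "like", "just", "well", "good", "okay", "fine",
    "things", "stuff", "people", "talk", "remember", "yesterday", "usually",
    "sometimes", "always", "never", "because", "school", "job", "music",
    "outside", "weekend")
}

#' Per-modality class-signal model for the generator
#'
#' Frame features are drawn as
#' `Normal(label * shift + session_effect, noise_sd^2)` with a per-session
#' random intercept `session_effect ~ Normal(0, session_sd^2)`; text signal is
#' the probability that a participant utterance contains a token from a fixed
#' marker lexicon (rate `text_marker_rate` for depressed sessions,
#' `text_marker_base` otherwise).
#'
#' Defaults place a moderate 0.15-SD shift on the first 12 audio features
#' (the MFCC block) and a 0.10-SD shift on 24 video features (the
#' action-unit block), with marker rates 0.35 vs 0.15.
#'
#' @param audio_shift length-74 vector of depressed-class mean offsets.
#' @param video_shift length-388 vector of offsets.
#' @param text_marker_rate marker-token probability for depressed utterances.
#' @param text_marker_base marker-token probability for non-depressed ones.
#' @param noise_sd within-session frame noise standard deviation (> 0).
#' @param session_sd between-session random-intercept standard deviation.
#' @return An object of class `signal_model`.
#' @export
signal_model <- function(audio_shift = c(rep(0.15, 12), rep(0, 62)),
                         video_shift = c(rep(0.10, 24), rep(0, 364)),
                         text_marker_rate = 0.35, text_marker_base = 0.15,
                         noise_sd = 1, session_sd = 0.3) {
  audio_shift <- rep_len(as.numeric(audio_shift), AUDIO_D)
  video_shift <- rep_len(as.numeric(video_shift), VIDEO_D)
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  for (r in c(text_marker_rate, text_marker_base))
    if (r < 0 || r > 1) stopf("marker rates must lie in [0, 1]")
  structure(list(audio_shift = audio_shift, video_shift = video_shift,
                 text_marker_rate = text_marker_rate,
                 text_marker_base = text_marker_base,
                 noise_sd = noise_sd, session_sd = session_sd),
            class = "signal_model")
}

#' A signal model with no class differences
#'
#' Convenience null model: zero feature shifts and equal marker rates, so any
#' classifier's held-out performance should sit in the permutation-null band.
#'
#' @param ... overrides passed to [signal_model()].
#' @export
null_signal <- function(...) {
  signal_model(audio_shift = 0, video_shift = 0,
               text_marker_rate = 0.15, text_marker_base = 0.15, ...)
}

.session_duration <- function(spec) {
  stats::runif(1L, spec$duration_range[1L], spec$duration_range[2L])
}

.gen_frames <- function(n, shifts, label, signal) {
  d <- length(shifts)
  sess <- stats::rnorm(d, 0, signal$session_sd)
  mu <- if (label == 1L) shifts + sess else sess
  m <- matrix(stats::rnorm(n * d, sd = signal$noise_sd), n, d)
  sweep(m, 2L, mu, "+")
}

.gen_transcript <- function(duration, label, spec, signal) {
  n_utt <- max(2L, round(duration / 60 * spec$utterance_rate))
  slot <- duration / n_utt
  starts <- (seq_len(n_utt) - 1L) * slot
  lens <- slot * stats::runif(n_utt, 0.70, 0.95)
  speaker <- rep_len(c("interviewer", "participant"), n_utt)
  rate <- if (label == 1L) signal$text_marker_rate else signal$text_marker_base
  base <- base_lexicon()
  markers <- marker_lexicon()
  texts <- vapply(seq_len(n_utt), function(i) {
    n_words <- sample(5:15, 1L)
    words <- sample(base, n_words, replace = TRUE)
    if (speaker[i] == "participant" && stats::runif(1L) < rate)
      words[sample.int(n_words, 1L)] <- sample(markers, 1L)
    paste(words, collapse = " ")
  }, character(1L))
  data.frame(start_time = starts, stop_time = starts + lens,
             speaker = speaker, value = texts, stringsAsFactors = FALSE)
}

#' Generate one synthetic interview session
#'
#' Draws a session duration uniformly within the spec's range, frames for both
#' modalities from the signal model, and an alternating interviewer /
#' participant transcript whose participant utterances carry marker tokens at
#' the class-dependent rate. Deterministic given `seed`.
#'
#' @param label 1 = depressed, 0 = non-depressed.
#' @param spec a [cohort_spec()].
#' @param signal a [signal_model()].
#' @param seed integer seed for this session's private stream.
#' @param session_id identifier (default derived from seed).
#' @return A `session_bundle`.
#' @export
generate_session <- function(label, spec = cohort_spec(), signal = signal_model(),
                             seed = spec$seed, session_id = sprintf("S%05d", seed)) {
  label <- as.integer(label)
  with_seed(seed, {
    duration <- .session_duration(spec)
    n_audio <- round(duration / spec$audio_frame_period)
    n_video <- round(duration / spec$video_frame_period)
    audio <- frame_table(.gen_frames(n_audio, signal$audio_shift, label, signal),
                         spec$audio_frame_period)
    video <- frame_table(.gen_frames(n_video, signal$video_shift, label, signal),
                         spec$video_frame_period)
    transcript <- .gen_transcript(duration, label, spec, signal)
    session_bundle(session_id, transcript, audio, video, label, duration)
  })
}

#' Generate a synthetic cohort
#'
#' Draws the cohort index first — exactly
#' `round(n_sessions * depressed_fraction)` depressed sessions in a seeded
#' random order, one derived seed per session — then (optionally) materializes
#' each session. With `dir = NULL` only the index is returned; each session
#' can be regenerated on demand from its stored seed via
#' [materialize_session()], which keeps arbitrarily long cohorts cheap to
#' index. With a directory, every bundle is written to disk and its path
#' recorded.
#'
#' @param spec a [cohort_spec()].
#' @param signal a [signal_model()].
#' @param dir optional output directory for the session bundles.
#' @return A `cohort_index` with columns `session_id`, `label`, `duration`,
#'   `seed`, `path`.
#' @export
generate_cohort <- function(spec = cohort_spec(), signal = signal_model(),
                            dir = NULL) {
  n <- spec$n_sessions
  if (n < 2L) stopf("a cohort needs at least 2 sessions, got %d", n)
  n_dep <- round(n * spec$depressed_fraction)
  idx <- with_seed(spec$seed, {
    labels <- integer(n)
    labels[sample.int(n, n_dep)] <- 1L
    seeds <- vapply(seq_len(n), function(i) derive_seed(spec$seed, i), integer(1L))
    ids <- sprintf("S%04d", seq_len(n))
    durations <- vapply(seeds, function(s) with_seed(s, .session_duration(spec)),
                        numeric(1L))
    data.frame(session_id = ids, label = labels, duration = durations,
               seed = seeds, path = NA_character_, stringsAsFactors = FALSE)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      b <- generate_session(idx$label[i], spec, signal, seed = idx$seed[i],
                            session_id = idx$session_id[i])
      write_session_bundle(b, dir)
      idx$path[i] <- dir
    }
  }
  out <- cohort_index(idx)
  attr(out, "spec") <- spec
  attr(out, "signal") <- signal
  out
}

#' Materialize one session of a generated cohort
#'
#' Regenerates (from the per-session seed) or reads back (from disk) the
#' `session_bundle` for one row of a cohort index.
#'
#' @param index a `cohort_index` from [generate_cohort()].
#' @param i row number or session id.
#' @param spec,signal generator parameters; defaults to those stored on the
#'   index.
#' @return A `session_bundle`.
#' @export
materialize_session <- function(index, i, spec = attr(index, "spec"),
                                signal = attr(index, "signal")) {
  if (is.character(i)) i <- match(i, index$session_id)
  row <- index[i, , drop = FALSE]
  if (!is.na(row$path) && dir.exists(row$path))
    return(read_session_bundle(row$path, row$session_id))
  if (is.null(spec) || is.null(signal))
    stopf("session %s has no on-disk path and the index carries no generator spec",
          row$session_id)
  generate_session(row$label, spec, signal, seed = row$seed,
                   session_id = row$session_id)
}

#' Materialize every session of a cohort as a list
#'
#' @inheritParams materialize_session
#' @return A named list of `session_bundle`s in index order.
#' @export
materialize_cohort <- function(index, spec = attr(index, "spec"),
                               signal = attr(index, "signal")) {
  out <- lapply(seq_len(nrow(index)), materialize_session, index = index,
                spec = spec, signal = signal)
  names(out) <- index$session_id
  out
}

#' Summarize a cohort's ground truth
#'
#' Class counts and duration statistics for a cohort index. When the index
#' references on-disk bundles, labels are re-read from the per-session meta
#' files and checked against the index; missing files raise an error naming
#' the affected sessions.
#'
#' @param index a `cohort_index`.
#' @return A list with `class_counts`, `n_sessions` and `duration` summary
#'   (min/median/max seconds).
#' @export
ground_truth_summary <- function(index) {
  if (nrow(index)) {
    on_disk <- which(!is.na(index$path))
    if (length(on_disk)) {
      meta_paths <- file.path(index$path[on_disk],
                              paste0(index$session_id[on_disk], "_meta.csv"))
      gone <- !file.exists(meta_paths)
      if (any(gone))
        stopf("missing session file(s): %s",
              paste(index$session_id[on_disk][gone], collapse = ", "))
      disk_labels <- vapply(meta_paths, function(p)
        as.integer(utils::read.csv(p)$label), integer(1L))
      if (!all(disk_labels == index$label[on_disk]))
        stopf("on-disk labels disagree with the index for session(s): %s",
              paste(index$session_id[on_disk][disk_labels != index$label[on_disk]],
                    collapse = ", "))
    }
  }
  dur <- if (nrow(index) && !is.null(index$duration)) index$duration else numeric()
  list(class_counts = class_counts(index), n_sessions = nrow(index),
       duration = c(min = if (length(dur)) min(dur) else NA_real_,
                    median = if (length(dur)) stats::median(dur) else NA_real_,
                    max = if (length(dur)) max(dur) else NA_real_))
}
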