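## Reading, writing and validating interview session bundles.
##
## A session bundle mirrors the layout of a DAIC-WOZ-style corpus entry:
## a timestamped transcript CSV, a framewise audio-feature matrix (74 columns,
## one row per 10 ms frame), a framewise video-feature matrix (388 columns)
## and a binary depression label.

AUDIO_D <- 74L
VIDEO_D <- 388L

#' Construct a framewise feature table
#'
#' A frame table is a numeric matrix with one row per frame at a fixed frame
#' period, e.g. 74 audio features per 10 ms frame or 388 video features per
#' 1/30 s frame.
#'
#' @param features numeric matrix, `n_frames x d`.
#' @param frame_period frame spacing in seconds (audio default 0.010).
#' @return An object of class `frame_table`.
#' @export
frame_table <- function(features, frame_period) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 1L) stopf("frame table must contain at least one frame")
  if (anyNA(features)) stopf("frame table contains missing values after validation")
  if (!is.numeric(frame_period) || frame_period <= 0)
    stopf("frame_period must be a positive number of seconds")
  structure(list(features = features, frame_period = frame_period),
            class = "frame_table")
}

#' @export
print.frame_table <- function(x, ...) {
  cat(sprintf("<frame_table> %d frames x %d features, period %.4g s (%.4g s total)\n",
              nrow(x$features), ncol(x$features), x$frame_period,
              nrow(x$features) * x$frame_period))
  invisible(x)
}

#' Number of frames in a frame table
#' @param x a `frame_table`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) nrow(x$features)

#' Construct a session bundle
#'
#' One clinical-interview session: transcript records, audio and video frame
#' tables, and a binary depression label (1 = depressed, 0 = non-depressed).
#'
#' @param session_id character scalar.
#' @param transcript data.frame with columns `start_time`, `stop_time`,
#'   `speaker` (`"participant"`/`"interviewer"`) and `value` (utterance text).
#' @param audio,video `frame_table` objects (74 and 388 features wide).
#' @param label 0 or 1.
#' @param duration session length in seconds.
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(session_id, transcript, audio, video, label, duration) {
  b <- structure(list(session_id = as.character(session_id),
                      transcript = transcript, audio = audio, video = video,
                      label = as.integer(label), duration = as.numeric(duration)),
                 class = "session_bundle")
  validate_session_bundle(b)
  b
}

#' Validate a session bundle's invariants
#'
#' Checks modality widths (audio 74, video 388), transcript time ordering
#' (`stop_time > start_time`, non-empty text), that no utterance extends past
#' the session duration, and that the audio frame count is consistent with
#' the duration at the declared frame period (to within one frame).
#'
#' @param b a `session_bundle`.
#' @return `b`, invisibly; errors describe the first violated invariant.
#' @export
validate_session_bundle <- function(b) {
  if (!b$label %in% c(0L, 1L)) stopf("label must be 0 or 1, got %s", b$label)
  if (ncol(b$audio$features) != AUDIO_D)
    stopf("audio width %d != %d", ncol(b$audio$features), AUDIO_D)
  if (ncol(b$video$features) != VIDEO_D)
    stopf("video width %d != %d", ncol(b$video$features), VIDEO_D)
  tr <- b$transcript
  if (nrow(tr)) {
    bad <- which(tr$stop_time <= tr$start_time)
    if (length(bad)) stopf("transcript row %d: stop_time <= start_time", bad[1L])
    if (any(!nzchar(trimws(tr$value))))
      stopf("transcript row %d: empty text", which(!nzchar(trimws(tr$value)))[1L])
    if (max(tr$stop_time) > b$duration + 1e-9)
      stopf("transcript extends past session duration (%.3f > %.3f)",
            max(tr$stop_time), b$duration)
  }
  expect_frames <- b$duration / b$audio$frame_period
  if (abs(n_frames(b$audio) - expect_frames) > 1 + 1e-6)
    stopf("audio frame count %d inconsistent with duration %.2f s at period %.3f s",
          n_frames(b$audio), b$duration, b$audio$frame_period)
  invisible(b)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %s: %.1f s, label %d (%s)\n", x$session_id,
              x$duration, x$label, if (x$label == 1L) "depressed" else "non-depressed"))
  cat(sprintf("  transcript: %d utterances (%d participant)\n", nrow(x$transcript),
              sum(x$transcript$speaker == "participant")))
  cat(sprintf("  audio: %d frames x %d; video: %d frames x %d\n",
              n_frames(x$audio), ncol(x$audio$features),
              n_frames(x$video), ncol(x$video$features)))
  invisible(x)
}

.read_delim <- function(path, dialect = c("csv", "tsv"), header = TRUE) {
  dialect <- match.arg(dialect)
  utils::read.table(path, header = header, sep = if (dialect == "csv") "," else "\t",
                    quote = "\"", stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a timestamped transcript
#'
#' Reads a transcript CSV with columns `start_time`, `stop_time`, `speaker`
#' and `value`, maps speaker strings onto the participant/interviewer
#' dichotomy, validates timing, and returns records sorted by start time.
#'
#' @param path file path.
#' @param participant_labels speaker strings mapped to `"participant"`; any
#'   other string maps to `"interviewer"`.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return data.frame with columns `start_time`, `stop_time`, `speaker`,
#'   `value`, sorted by `start_time`.
#' @export
read_transcript <- function(path, participant_labels = "Participant",
                            dialect = c("csv", "tsv")) {
  if (!file.exists(path)) stopf("transcript file not found: %s", path)
  df <- .read_delim(path, dialect)
  required <- c("start_time", "stop_time", "speaker", "value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("transcript %s: missing column(s): %s", path, paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    return(data.frame(start_time = numeric(), stop_time = numeric(),
                      speaker = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  for (col in c("start_time", "stop_time")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stopf("transcript %s row %d: unparseable %s '%s'", path, bad[1L], col,
            df[[col]][bad[1L]])
    df[[col]] <- v
  }
  bad <- which(df$stop_time <= df$start_time)
  if (length(bad))
    stopf("transcript %s row %d: stop_time (%.3f) <= start_time (%.3f)",
          path, bad[1L], df$stop_time[bad[1L]], df$start_time[bad[1L]])
  if (any(df$start_time < 0))
    stopf("transcript %s row %d: negative start_time", path, which(df$start_time < 0)[1L])
  blank <- which(!nzchar(trimws(as.character(df$value))))
  if (length(blank))
    stopf("transcript %s row %d: empty utterance text", path, blank[1L])
  df$speaker <- ifelse(as.character(df$speaker) %in% participant_labels,
                       "participant", "interviewer")
  df <- df[order(df$start_time), required, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a framewise feature matrix
#'
#' Reads a delimiter-separated numeric matrix (one row per frame), verifies
#' its width against the modality's declared feature count, and imputes
#' missing cells by previous-frame carry-forward (zeros for the first frame).
#' A header row is detected automatically.
#'
#' @param path file path.
#' @param expected_d required number of feature columns (74 audio, 388 video).
#' @param frame_period frame spacing in seconds.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A `frame_table`.
#' @export
read_frame_table <- function(path, expected_d, frame_period,
                             dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("frame table file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (dialect == "csv") "," else "\t"
  toks <- strsplit(first, sep, fixed = TRUE)[[1L]]
  ## header iff the first line holds tokens that are neither numbers nor
  ## missing-value markers
  numeric_like <- !is.na(suppressWarnings(as.numeric(toks))) |
    toupper(trimws(toks)) %in% c("NA", "NAN", "")
  has_header <- any(!numeric_like)
  df <- .read_delim(path, dialect, header = has_header)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (ncol(m) != expected_d)
    stopf("frame table %s: width %d != %d", path, ncol(m), expected_d)
  if (anyNA(m)) {
    n_missing <- sum(is.na(m))
    for (j in seq_len(ncol(m))) {
      nas <- which(is.na(m[, j]))
      for (i in nas) m[i, j] <- if (i == 1L) 0 else m[i - 1L, j]
    }
    message(sprintf("frame table %s: imputed %d missing cell(s) by carry-forward",
                    path, n_missing))
  }
  dimnames(m) <- NULL
  frame_table(m, frame_period)
}

bundle_paths <- function(session_id) {
  c(meta = paste0(session_id, "_meta.csv"),
    transcript = paste0(session_id, "_transcript.csv"),
    audio = paste0(session_id, "_audio.csv"),
    video = paste0(session_id, "_video.csv"))
}

.write_matrix <- function(m, path) {
  txt <- apply(m, 1L, function(r) paste(format_num(r), collapse = ","))
  writeLines(txt, path, useBytes = TRUE)
}

#' Write a session bundle to a directory
#'
#' Serializes one session as four CSV files (`<id>_meta.csv`,
#' `<id>_transcript.csv`, `<id>_audio.csv`, `<id>_video.csv`). Numeric values
#' are written with enough precision that reading them back reproduces the
#' bundle bit-exactly. Existing files for the same id are overwritten with a
#' warning.
#'
#' @param bundle a `session_bundle`.
#' @param dir output directory (created if absent).
#' @return Named character vector of the four paths relative to `dir`.
#' @export
write_session_bundle <- function(bundle, dir) {
  validate_session_bundle(bundle)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rel <- bundle_paths(bundle$session_id)
  paths <- stats::setNames(file.path(dir, rel), names(rel))
  if (any(file.exists(paths)))
    warnf("overwriting existing files for session %s in %s", bundle$session_id, dir)
  meta <- data.frame(session_id = bundle$session_id, label = bundle$label,
                     duration = format_num(bundle$duration),
                     audio_frame_period = format_num(bundle$audio$frame_period),
                     video_frame_period = format_num(bundle$video$frame_period))
  utils::write.csv(meta, paths[["meta"]], row.names = FALSE, quote = FALSE)
  tr <- bundle$transcript
  tr_out <- data.frame(start_time = format_num(tr$start_time),
                       stop_time = format_num(tr$stop_time),
                       speaker = tr$speaker, value = tr$value,
                       stringsAsFactors = FALSE)
  utils::write.csv(tr_out, paths[["transcript"]], row.names = FALSE, quote = TRUE)
  .write_matrix(bundle$audio$features, paths[["audio"]])
  .write_matrix(bundle$video$features, paths[["video"]])
  rel
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir directory containing the four per-session CSV files.
#' @param session_id session identifier.
#' @return A `session_bundle`.
#' @export
read_session_bundle <- function(dir, session_id) {
  rel <- bundle_paths(session_id)
  paths <- stats::setNames(file.path(dir, rel), names(rel))
  missing <- rel[!file.exists(paths)]
  if (length(missing))
    stopf("session %s: missing file(s) in %s: %s", session_id, dir,
          paste(missing, collapse = ", "))
  meta <- utils::read.csv(paths[["meta"]], stringsAsFactors = FALSE)
  tr <- read_transcript(paths[["transcript"]],
                        participant_labels = c("Participant", "participant"))
  audio <- read_frame_table(paths[["audio"]], AUDIO_D,
                            as.numeric(meta$audio_frame_period))
  video <- read_frame_table(paths[["video"]], VIDEO_D,
                            as.numeric(meta$video_frame_period))
  session_bundle(meta$session_id, tr, audio, video, meta$label,
                 as.numeric(meta$duration))
}

#' Construct a cohort index
#'
#' The index of a cohort: one row per session with its id, label, duration
#' in seconds, the per-session generator seed (when generated synthetically)
#' and the on-disk path (when written).
#'
#' @param entries data.frame with at least `session_id` and `label`.
#' @return A `cohort_index` (a classed data.frame).
#' @export
cohort_index <- function(entries) {
  stopifnot(all(c("session_id", "label") %in% names(entries)))
  if (anyDuplicated(entries$session_id))
    stopf("duplicate session_id in cohort index: %s",
          entries$session_id[duplicated(entries$session_id)][1L])
  if (!all(entries$label %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (is.null(entries$path)) entries$path <- NA_character_
  class(entries) <- c("cohort_index", "data.frame")
  entries
}

#' @export
print.cohort_index <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<cohort_index> %d sessions: %d depressed / %d non-depressed\n",
              nrow(x), cc[["depressed"]], cc[["non_depressed"]]))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Class counts of a cohort index
#' @param index a `cohort_index`.
#' @return Named integer vector `c(non_depressed, depressed)`.
#' @export
class_counts <- function(index) {
  c(non_depressed = sum(index$label == 0L), depressed = sum(index$label == 1L))
}

#' Write / read a cohort index CSV
#'
#' @param index a `cohort_index`.
#' @param path CSV path with columns `session_id`, `path`, `label` (plus
#'   `duration` and `seed` when available).
#' @return `write_cohort_index` returns `path` invisibly; `read_cohort_index`
#'   returns a `cohort_index`.
#' @export
write_cohort_index <- function(index, path) {
  df <- as.data.frame(index)
  num_cols <- intersect(c("duration"), names(df))
  for (col in num_cols) df[[col]] <- format_num(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_index
#' @export
read_cohort_index <- function(path) {
  if (!file.exists(path)) stopf("cohort index not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$duration)) df$duration <- as.numeric(df$duration)
  df$label <- as.integer(df$label)
  cohort_index(df)
}
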