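## Desk-scale fixtures built in code.

## A small cohort with short sessions; signal controllable per modality.
desk_cohort <- function(n = 12L, seed = 7L, duration = c(30, 60),
                        audio_shift = 0, video_shift = 0,
                        marker_rate = 0.15, marker_base = 0.15,
                        depressed_fraction = 0.5, session_sd = 0.3) {
  spec <- cohort_spec(n_sessions = n, depressed_fraction = depressed_fraction,
                      duration_range = duration, seed = seed)
  sig <- signal_model(audio_shift = audio_shift, video_shift = video_shift,
                      text_marker_rate = marker_rate,
                      text_marker_base = marker_base, session_sd = session_sd)
  idx <- generate_cohort(spec, sig)
  list(index = idx, bundles = materialize_cohort(idx), spec = spec, signal = sig)
}

## Directly built aligned sessions (bypassing generation) for network tests.
fake_aligned <- function(L, label, audio_mean = 0, video_mean = 0,
                         text_mean = 0, id = "fake") {
  structure(list(text_seq = matrix(rnorm(L * 301, text_mean), L, 301),
                 audio_seq = matrix(rnorm(L * 74, audio_mean), L, 74),
                 video_seq = matrix(rnorm(L * 388, video_mean), L, 388),
                 valid_steps = L, label = as.integer(label), L = as.integer(L),
                 session_id = id, level = "sentence"),
            class = "aligned_session")
}

fake_aligned_set <- function(n, L, shift = 1.5, modality = "audio", seed = 1L) {
  set.seed(seed)
  labels <- rep_len(c(0L, 1L), n)
  lapply(seq_len(n), function(i) {
    lab <- labels[i]
    fake_aligned(L, lab,
                 audio_mean = if (modality == "audio") lab * shift else 0,
                 video_mean = if (modality == "video") lab * shift else 0,
                 text_mean = if (modality == "text") lab * shift else 0,
                 id = sprintf("F%03d", i))
  })
}

## A deterministic hand-written session bundle for io tests.
tiny_bundle <- function(id = "T001", label = 1L) {
  duration <- 10
  audio <- frame_table(matrix(seq_len(1000 * 74) %% 17 / 17, 1000, 74), 0.010)
  video <- frame_table(matrix(seq_len(300 * 388) %% 13 / 13, 300, 388), 1 / 30)
  tr <- data.frame(
    start_time = c(0.5, 3.0, 5.5, 8.0),
    stop_time = c(2.5, 5.0, 7.5, 9.5),
    speaker = c("interviewer", "participant", "interviewer", "participant"),
    value = c("how was your week", "it was fine i guess",
              "tell me more", "i felt tired most days"),
    stringsAsFactors = FALSE)
  session_bundle(id, tr, audio, video, label, duration)
}
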