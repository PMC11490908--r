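## YAML run configuration: cohort and signal parameters for the CLI.

#' Load generator configuration from YAML
#'
#' Reads a YAML file with optional `cohort:` and `signal:` blocks whose keys
#' match the arguments of [cohort_spec()] and [signal_model()].
#'
#' @param path YAML file path.
#' @return List with elements `spec` (a `cohort_spec`) and `signal`
#'   (a `signal_model`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  spec <- do.call(cohort_spec, cfg$cohort %||% list())
  signal <- do.call(signal_model, cfg$signal %||% list())
  list(spec = spec, signal = signal)
}

#' Write run metadata as YAML
#'
#' @param meta named list (stage, seed, counts, parameters...).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  yaml::write_yaml(meta, path)
  invisible(path)
}

## Structured one-line stage log.
log_stage <- function(stage, ...) {
  kv <- list(...)
  msg <- paste(vapply(names(kv), function(k) sprintf("%s=%s", k, kv[[k]]),
                      character(1L)), collapse = " ")
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}
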