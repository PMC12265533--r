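#' Read and write trial tables as CSV
#'
#' Thin wrappers around readr with schema checks: recognition tables
#' need `participant`, `condition`, `probe_status`, `bin`; change-
#' detection tables need `participant`, `stim_type`, `set_size`,
#' `change`, `said_change`.
#'
#' @param path CSV file path.
#' @param trials Trial tibble to write.
#' @param schema `"recognition"`, `"change"`, or `"any"` (no check).
#' @return `read_trials()` returns a tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
read_trials <- function(path, schema = c("recognition", "change", "any")) {
  schema <- match.arg(schema)
  trials <- readr::read_csv(path, show_col_types = FALSE)
  check_trial_schema(trials, schema)
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

check_trial_schema <- function(trials, schema) {
  cols <- switch(schema,
                 recognition = c("participant", "condition", "probe_status",
                                 "bin"),
                 change = c("participant", "stim_type", "set_size", "change",
                            "said_change"),
                 any = character(0))
  require_columns(trials, cols, "trial table")
  invisible(trials)
}
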