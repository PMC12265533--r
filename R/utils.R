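# internal validation helpers ------------------------------------------------

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "wmcda_validation_error")
}

check_prob <- function(x, field, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) stop_field(field, "must be numeric with no NA")
  if (!is.null(len) && length(x) != len)
    stop_field(field, sprintf("must have length %d", len))
  if (any(x < 0 | x > 1)) stop_field(field, "must lie in [0, 1]")
  x
}

check_positive_int <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop_field(field, "must be a single positive integer")
  as.integer(x)
}

check_increasing <- function(x, field) {
  if (!is.numeric(x) || anyNA(x)) stop_field(field, "must be numeric with no NA")
  if (any(diff(x) <= 0)) stop_field(field, "must be strictly increasing")
  x
}

check_nonneg <- function(x, field, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) stop_field(field, "must be numeric with no NA")
  if (!is.null(len) && length(x) != len)
    stop_field(field, sprintf("must have length %d", len))
  if (any(x < 0)) stop_field(field, "must be non-negative")
  x
}

require_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L)
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "wmcda_schema_error")
  invisible(data)
}

# zero-padded participant labels: p01, p02, ...
participant_labels <- function(n) {
  sprintf("p%0*d", max(2L, nchar(n)), seq_len(n))
}
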