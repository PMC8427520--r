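# Validation errors carry a dedicated condition class so callers (and the
# command-line wrapper, which maps them to exit code 2) can distinguish bad
# user input from runtime failures.

stop_validation <- function(msg, field = NULL, call. = FALSE) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  stop(structure(
    class = c("sumdr_validation_error", "error", "condition"),
    list(message = msg, call = NULL, field = field)
  ))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(sprintf("'%s' must be a single finite number", name), name)
  if (positive && x <= 0)
    stop_validation(sprintf("'%s' must be > 0", name), name)
  if (nonneg && x < 0)
    stop_validation(sprintf("'%s' must be >= 0", name), name)
  invisible(x)
}

# duration must be an integer multiple of unit (within floating tolerance)
check_commensurate <- function(duration, unit, dname, uname) {
  ratio <- duration / unit
  if (abs(ratio - round(ratio)) > 1e-8 || round(ratio) < 1)
    stop_validation(sprintf("'%s' (%g) must be a positive integer multiple of '%s' (%g)",
                            dname, duration, uname, unit), dname)
  as.integer(round(ratio))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
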