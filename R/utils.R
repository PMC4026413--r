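#' @keywords internal
"_PACKAGE"

# Shared argument checks. All validation errors are classed so callers can
# distinguish bad inputs from numerical failures.

lel_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lel_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != floor(x) || x < min) {
    lel_error("lel_invalid_config", sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 0 || x > 1) {
    lel_error("lel_invalid_config", sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 0) {
    lel_error("lel_invalid_config", sprintf("`%s` must be a single non-negative number", name))
  }
  as.numeric(x)
}

#' Normalize gene symbols
#'
#' Gene symbols are upper-cased and stripped of surrounding whitespace at
#' every list boundary so that case and formatting differences between
#' studies do not break overlap computations.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}
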