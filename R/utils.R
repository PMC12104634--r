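# shared validation helpers

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s, got %s",
      name, if (strict_lower) "(" else "[", format(lower), format(upper),
      if (strict_upper) ")" else "]", paste(format(x), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

assert_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) abort(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(TRUE)
}

assert_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# euclidean distance between point sets given as equal-length x/y vectors
euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
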