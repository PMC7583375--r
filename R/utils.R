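`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in the pipeline flows from one root seed; each stage draws
#' from its own substream so stages are independently reproducible.
#'
#' @param seed integer root seed.
#' @param stream character stage name.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((abs(seed) + h) %% .Machine$integer.max)
}

# check a numeric vector is a probability simplex
is_simplex <- function(x, tol = 1e-9) {
  all(x >= -tol) && abs(sum(x) - 1) <= tol
}

assert_simplex <- function(x, what = "proportions", tol = 1e-9) {
  if (!is_simplex(x, tol)) {
    stop(sprintf("%s must be nonnegative and sum to 1 (got sum = %.12g)",
                 what, sum(x)), call. = FALSE)
  }
  invisible(x)
}

#' Assign lengths to 10-cm fork-length bins
#'
#' Bins are half-open, closed on the left: [0, 10), [10, 20), ...
#'
#' @param length_cm numeric fork lengths (cm).
#' @param width bin width in cm (default 10).
#' @return Integer lower bin edge for each length.
#' @export
length_bin <- function(length_cm, width = 10) {
  as.integer(floor(length_cm / width) * width)
}

# grams per megagram
MG_TO_G <- 1e6

age_class_levels <- function() c("0", "1", "2", "3+")
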