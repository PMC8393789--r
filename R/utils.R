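# Classed conditions so callers (and the CLI) can react to the failing
# precondition rather than pattern-match messages.

stop_constant_input <- function(what) {
  abort(sprintf("`%s` is constant; a non-degenerate series is required.", what),
        class = "liv_error_constant_input")
}

stop_insufficient_sample <- function(n, min_n) {
  abort(sprintf("sample size %d is below the minimum of %d complete rows.", n, min_n),
        class = "liv_error_insufficient_sample")
}

stop_length_mismatch <- function(...) {
  lens <- c(...)
  abort(sprintf("input series have mismatched lengths (%s).",
                paste(lens, collapse = ", ")),
        class = "liv_error_length_mismatch")
}

stop_degenerate_table <- function() {
  abort("degenerate contingency table: no stratum has 2 or more nonzero rows and columns (0 degrees of freedom).",
        class = "liv_error_degenerate_table")
}

stop_format <- function(msg) abort(msg, class = "liv_error_format")

stop_multivariate <- function(msg) {
  abort(msg, class = c("liv_error_multivariate", "liv_error_format"))
}

stop_missing_meta <- function(msg) abort(msg, class = "liv_error_missing_meta")

stop_invalid_config <- function(msg, class = "liv_error_invalid_config") {
  abort(msg, class = class)
}

is_constant <- function(v, tol = 0) {
  if (length(v) == 0L) return(TRUE)
  diff(range(v)) <= tol
}

#' Coerce a data frame to a validated bivariate sample
#'
#' Takes the first two numeric columns of `data` as the observed series X and
#' Y, drops rows with missing values, and checks the minimum sample size
#' required by the conditional-independence tests.
#'
#' @param data A data frame whose first two columns are the numeric series X
#'   and Y (extra columns are ignored).
#' @param min_n Minimum number of complete rows (default 8, the smallest size
#'   for which the partial-correlation t-test has at least 5 degrees of
#'   freedom).
#' @return A tibble with columns `x` and `y` and only complete rows.
#' @export
as_bivariate <- function(data, min_n = 8L) {
  if (!is.data.frame(data) || ncol(data) < 2L) {
    stop_format("`data` must be a data frame with at least two columns (X then Y).")
  }
  x <- data[[1L]]
  y <- data[[2L]]
  if (!is.numeric(x) || !is.numeric(y)) {
    stop_format("the first two columns of `data` must be numeric.")
  }
  keep <- is.finite(x) & is.finite(y)
  out <- tibble::tibble(x = as.numeric(x[keep]), y = as.numeric(y[keep]))
  if (nrow(out) < min_n) stop_insufficient_sample(nrow(out), min_n)
  out
}

# Deterministic sub-seed derivation: one master seed, fixed documented
# offsets, kept well inside 32-bit integer range.
derive_seed <- function(seed, stream, index = 0L) {
  offset <- switch(stream,
    cluster_x = 1L, cluster_y = 2L, cluster_joint = 3L,
    fold = 97L, replicate = 7919L, pair = 131L, permute = 11L,
    abort(sprintf("unknown seed stream '%s'", stream))
  )
  (as.integer(seed) + offset * (as.integer(index) + 1L)) %% 2147483647L
}
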