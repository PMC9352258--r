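#' Uniformly sampled current trace
#'
#' Container for a single-channel current recording: a numeric vector of
#' currents in pA, a sampling frequency in Hz and a start time in
#' seconds. Sample `i` (1-based) corresponds to time
#' `t0 + (i - 1) / fs`. Windows into a trace are 1-based half-open
#' sample intervals `[start, end)`.
#'
#' @param current Numeric vector of currents, pA; length >= 2.
#' @param fs Sampling frequency, Hz; > 0.
#' @param t0 Time of the first sample, s.
#' @return An object of class `nanopore_trace`.
#' @export
nanopore_trace <- function(current, fs, t0 = 0) {
  if (!is.numeric(current) || length(current) < 2L)
    stop("current must be a numeric vector of length >= 2", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  structure(list(current = as.numeric(current), fs = fs, t0 = t0),
            class = "nanopore_trace")
}

#' @export
print.nanopore_trace <- function(x, ...) {
  n <- length(x$current)
  cat(sprintf(
    "nanopore trace: %d samples at %.6g Hz (%.4g s), t0 = %.6g s\n",
    n, x$fs, n / x$fs, x$t0))
  cat(sprintf("  current range: [%.4g, %.4g] pA\n",
              min(x$current), max(x$current)))
  invisible(x)
}

#' @export
length.nanopore_trace <- function(x) length(x$current)

#' Sample times of a trace
#'
#' @param trace A [nanopore_trace()].
#' @return Numeric vector of times, s.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "nanopore_trace"))
  trace$t0 + (seq_along(trace$current) - 1) / trace$fs
}

#' Convert sample index to time and back
#'
#' @param trace A [nanopore_trace()].
#' @param index 1-based sample index.
#' @return `index_to_time` returns seconds; `time_to_index` the nearest
#'   1-based sample index.
#' @export
index_to_time <- function(trace, index) trace$t0 + (index - 1) / trace$fs

#' @rdname index_to_time
#' @param time Time, s.
#' @export
time_to_index <- function(trace, time) {
  round((time - trace$t0) * trace$fs) + 1
}
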