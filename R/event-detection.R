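#' Robust open-pore baseline and noise estimate
#'
#' The open-pore level is tracked with a rolling median (robust against
#' blockades at low duty cycle) and the noise standard deviation with
#' 1.4826 times the median absolute deviation of the residual. Traces
#' shorter than the rolling window fall back to a global median with a
#' warning.
#'
#' @param trace A [nanopore_trace()], at least 100 samples.
#' @param window Rolling-median window length in samples (forced odd);
#'   default 10001.
#' @return A list with `mean` (global open-pore level, pA), `sd` (noise
#'   SD, pA) and `level` (the per-sample rolling baseline, pA).
#' @export
estimate_baseline <- function(trace, window = 10001L) {
  stopifnot(inherits(trace, "nanopore_trace"))
  x <- trace$current
  n <- length(x)
  if (n < 100L) stop("trace too short for baseline estimation", call. = FALSE)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (n < window) {
    warning("trace shorter than baseline window; using global median",
            call. = FALSE)
    level <- rep(stats::median(x), n)
  } else {
    level <- stats::runmed(x, k = window, endrule = "median")
  }
  resid <- x - level
  list(mean = stats::median(x),
       sd = stats::mad(resid, center = 0),
       level = as.numeric(level))
}

#' Localize candidate blockades by robust threshold crossing
#'
#' A window opens when the current crosses `baseline - k * sd` (for
#' downward blockades; mirrored for `direction = "up"`) and closes when
#' the signal re-enters within one noise SD of the baseline. Windows
#' separated by fewer than `merge_gap` samples are merged. Detection is
#' localization only: the amplitudes seen here are never reused for
#' characterization, which refits the full model.
#'
#' @param trace A [nanopore_trace()] (typically after a low-pass
#'   localization filter, e.g. 5 kHz).
#' @param threshold_k Opening threshold in noise SDs; default 5.
#' @param merge_gap Windows closer than this many samples are merged.
#' @param baseline_window Rolling-median window for
#'   [estimate_baseline()].
#' @param direction `"down"` for blockades that reduce the current
#'   (default), `"up"` for enhancements.
#' @param baseline Optional precomputed result of [estimate_baseline()].
#' @return A `data.frame` with one row per window: `start`, `end`
#'   (1-based half-open sample interval), `baseline_mean`,
#'   `baseline_sd`. Rows are ordered and disjoint; zero rows when
#'   nothing crosses the threshold.
#' @export
detect_events <- function(trace, threshold_k = 5, merge_gap = 10L,
                          baseline_window = 10001L,
                          direction = c("down", "up"),
                          baseline = NULL) {
  stopifnot(inherits(trace, "nanopore_trace"))
  direction <- match.arg(direction)
  if (is.null(baseline))
    baseline <- estimate_baseline(trace, baseline_window)
  x <- trace$current
  if (direction == "up") {
    x <- -x
    level <- -baseline$level
  } else {
    level <- baseline$level
  }
  sd <- baseline$sd
  n <- length(x)
  empty <- data.frame(start = integer(), end = integer(),
                      baseline_mean = numeric(), baseline_sd = numeric())
  if (sd == 0) {
    below <- x < level
  } else {
    below <- x < level - threshold_k * sd
  }
  if (!any(below)) return(empty)
  opens <- which(below & !c(FALSE, below[-n]))
  reentry <- which(x >= level - sd)
  starts <- integer(0); ends <- integer(0)
  last_end <- 0L
  for (s in opens) {
    if (s < last_end) next            # inside the previous window
    j <- reentry[reentry > s]
    e <- if (length(j)) j[1] else n + 1L   # half-open end
    starts <- c(starts, s); ends <- c(ends, e)
    last_end <- e
  }
  # merge windows separated by fewer than merge_gap samples
  if (length(starts) > 1L) {
    keep_s <- starts[1]; out_s <- integer(0); out_e <- integer(0)
    cur_e <- ends[1]
    for (i in seq_along(starts)[-1]) {
      if (starts[i] - cur_e < merge_gap) {
        cur_e <- ends[i]
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
        keep_s <- starts[i]; cur_e <- ends[i]
      }
    }
    out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
    starts <- out_s; ends <- out_e
  }
  data.frame(start = starts, end = pmin(ends, n + 1L),
             baseline_mean = baseline$mean, baseline_sd = sd)
}
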