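#' Detect, fit and characterize all events in a trace
#'
#' The full analysis pipeline: events are localized on a low-pass
#' filtered copy of the trace (localization only; its amplitudes are
#' never reused), then each detection window is refitted with the
#' five-parameter model on the characterization trace (the raw trace,
#' or a copy filtered at `char_cutoff`), and the derived features are
#' computed from the fit.
#'
#' @param trace A [nanopore_trace()].
#' @param loc_cutoff Localization Gaussian filter cutoff, Hz (default
#'   5 kHz); `NULL` to detect on the unfiltered trace.
#' @param char_cutoff Characterization Gaussian filter cutoff, Hz;
#'   `NULL` to fit the raw trace.
#' @param control A [fit_control()].
#' @param threshold_k,merge_gap,baseline_window,direction Passed to
#'   [detect_events()].
#' @param windows Optional precomputed detection table (as returned by
#'   [detect_events()]); skips detection when given.
#' @param trace_id Identifier stored with the events.
#' @return A `data.frame` with one row per detection: window times and
#'   baseline statistics, the five fitted parameters with diagnostics
#'   (`rmse`, `converged`, `n_iter`, `at_bound`, `non_event`), and the
#'   derived features of [event_features()]. Zero rows when nothing is
#'   detected.
#' @export
characterize_events <- function(trace, loc_cutoff = 5000,
                                char_cutoff = NULL,
                                control = fit_control(),
                                threshold_k = 5, merge_gap = 10L,
                                baseline_window = 10001L,
                                direction = c("down", "up"),
                                windows = NULL, trace_id = "trace") {
  stopifnot(inherits(trace, "nanopore_trace"))
  direction <- match.arg(direction)
  if (is.null(windows)) {
    loc_trace <- if (is.null(loc_cutoff)) trace
                 else gaussian_lowpass(trace, loc_cutoff)
    windows <- detect_events(loc_trace, threshold_k = threshold_k,
                             merge_gap = merge_gap,
                             baseline_window = baseline_window,
                             direction = direction)
  }
  char_trace <- if (is.null(char_cutoff)) trace
                else gaussian_lowpass(trace, char_cutoff)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    fit <- tryCatch(
      fit_event(char_trace, w$start, w$end, control = control,
                direction = direction),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    feats <- event_features(fit$params, fit$t_start, fit$t_end,
                            p = control$p, p_max = control$p_max,
                            rc_tau = control$rc_tau,
                            fs_mode = control$fs_mode,
                            beta_max = control$beta_max)
    cbind(
      data.frame(event_id = i, trace_id = trace_id,
                 t_start = fit$t_start, t_end = fit$t_end,
                 baseline_mean = w$baseline_mean,
                 baseline_sd = w$baseline_sd,
                 i_open = fit$params$i_open, di_b = fit$params$di_b,
                 mu = fit$params$mu, sigma = fit$params$sigma,
                 beta = fit$params$beta, rmse = fit$rmse,
                 converged = fit$converged, n_iter = fit$n_iter,
                 at_bound = paste(fit$at_bound, collapse = ","),
                 non_event = fit$non_event),
      feats)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- characterize_events_schema()
  } else {
    out <- do.call(rbind, rows)
    out$event_id <- seq_len(nrow(out))
  }
  rownames(out) <- NULL
  out
}

# zero-row event table with the full column set
characterize_events_schema <- function() {
  data.frame(event_id = integer(), trace_id = character(),
             t_start = numeric(), t_end = numeric(),
             baseline_mean = numeric(), baseline_sd = numeric(),
             i_open = numeric(), di_b = numeric(), mu = numeric(),
             sigma = numeric(), beta = numeric(), rmse = numeric(),
             converged = logical(), n_iter = integer(),
             at_bound = character(), non_event = logical(),
             dwell_time = numeric(), i_ex = numeric(), i_res = numeric(),
             fs_event = numeric(), fs_event_cdf = numeric(),
             fs_event_amp = numeric(), loc_valid = logical(),
             overlap_valid = logical(), p_threshold = numeric())
}

#' Sweep characterization filters and recommend a cutoff range
#'
#' Events are localized once (at `loc_cutoff`), then characterized at
#' each candidate cutoff. Per cutoff the sweep reports the median
#' per-event sampling frequency, median back-mapped dwell time, median
#' excluded current, median fitted amplitude and the fraction of events
#' passing the amplitude-overlap validation. The recommended lower
#' bound is the smallest cutoff whose median sampling frequency agrees
#' with the next cutoff up to within `rel_tol` (the over-filtering
#' regime below it elongates dwell times and depresses amplitudes); the
#' recommended upper bound is the largest cutoff before the median
#' fitted amplitude starts decreasing again, the signature of baseline
#' noise blending into the events under under-filtering. Cutoffs with
#' fewer than `min_events` usable fits are flagged unreliable and
#' excluded from bound selection.
#'
#' @param trace A [nanopore_trace()].
#' @param cutoffs At least three ascending candidate cutoffs, Hz.
#' @param loc_cutoff Localization filter cutoff, Hz.
#' @param rel_tol Relative stability tolerance on the median sampling
#'   frequency (default 0.1).
#' @param min_events Minimum usable events per cutoff.
#' @param control A [fit_control()]; the sampling-frequency reading
#'   used for stability is `control$fs_mode`.
#' @param ... Passed to [characterize_events()] (detection options).
#' @return A list with `lower`, `upper` (Hz, possibly `NA`) and
#'   `table`, the per-cutoff summary for auditing.
#' @export
recommend_filter <- function(trace, cutoffs, loc_cutoff = 5000,
                             rel_tol = 0.1, min_events = 5L,
                             control = fit_control(), ...) {
  stopifnot(inherits(trace, "nanopore_trace"))
  cutoffs <- sort(unique(as.numeric(cutoffs)))
  if (length(cutoffs) < 3L) stop("need at least 3 cutoffs", call. = FALSE)
  loc_trace <- gaussian_lowpass(trace, loc_cutoff)
  windows <- detect_events(loc_trace, ...)
  summ <- lapply(cutoffs, function(fc) {
    ev <- characterize_events(trace, char_cutoff = fc, control = control,
                              windows = windows)
    ev <- ev[ev$converged & !ev$non_event, , drop = FALSE]
    data.frame(
      cutoff = fc,
      n_events = nrow(ev),
      median_fs_event = stats::median(ev$fs_event, na.rm = TRUE),
      median_dwell = stats::median(ev$dwell_time, na.rm = TRUE),
      median_i_ex = stats::median(ev$i_ex, na.rm = TRUE),
      median_abs_di_b = stats::median(abs(ev$di_b), na.rm = TRUE),
      frac_overlap_valid = mean(ev$overlap_valid, na.rm = TRUE),
      reliable = nrow(ev) >= min_events
    )
  })
  tab <- do.call(rbind, summ)
  ok <- tab$reliable & is.finite(tab$median_fs_event)
  lower <- NA_real_
  idx <- which(ok)
  for (i in idx) {
    j <- idx[idx > i]
    if (!length(j)) break
    j <- j[1]
    if (abs(tab$median_fs_event[i] - tab$median_fs_event[j]) <
        rel_tol * tab$median_fs_event[j]) { lower <- tab$cutoff[i]; break }
  }
  upper <- NA_real_
  amp <- tab$median_abs_di_b
  cand <- which(ok)
  if (length(cand) >= 2L) {
    drop_at <- NA_integer_
    for (k in seq_along(cand)[-1]) {
      i <- cand[k]; i0 <- cand[k - 1]
      if (amp[i] < amp[i0] * (1 - rel_tol)) { drop_at <- k; break }
    }
    upper <- if (is.na(drop_at)) tab$cutoff[cand[length(cand)]]
             else tab$cutoff[cand[drop_at - 1L]]
  }
  list(lower = lower, upper = upper, table = tab)
}
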