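#' Store characterized events in a SQLite file
#'
#' Events are kept in three normalized tables — `detections` (window
#' times and baseline statistics), `fits` (the five parameters and fit
#' diagnostics) and `features` (derived per-event quantities) — plus a
#' `meta` key/value table holding a configuration snapshot, the package
#' version and the filters used. Keeping detections separate from the
#' optimized results lets the fit be validated against the raw
#' localization. Re-storing events for the same trace replaces rows by
#' `(trace_id, t_start)`, so re-runs are idempotent. The store is
#' written through the bundled Python-stdlib `sqlite3` helper.
#'
#' @param events Event table from [characterize_events()].
#' @param path SQLite file path (created if absent).
#' @param meta Named list of metadata to record (config snapshot,
#'   filters used, ...).
#' @return The number of detection rows written, invisibly.
#' @export
store_events <- function(events, path, meta = list()) {
  stopifnot(is.data.frame(events))
  tmp <- tempfile("gndfit-store-")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  det <- events[, intersect(c("event_id", "trace_id", "t_start", "t_end",
                              "baseline_mean", "baseline_sd"),
                            names(events)), drop = FALSE]
  fits <- events[, intersect(c("event_id", "i_open", "di_b", "mu", "sigma",
                               "beta", "rmse", "converged", "at_bound"),
                             names(events)), drop = FALSE]
  feats <- events[, intersect(c("event_id", "dwell_time", "i_ex",
                                "fs_event", "loc_valid", "overlap_valid",
                                "p_threshold"),
                              names(events)), drop = FALSE]
  if (nrow(fits)) {
    fits$converged <- as.integer(fits$converged)
    feats$loc_valid <- as.integer(feats$loc_valid)
    feats$overlap_valid <- as.integer(feats$overlap_valid)
  }
  paths <- file.path(tmp, c("detections.csv", "fits.csv", "features.csv"))
  utils::write.csv(det, paths[1], row.names = FALSE, na = "")
  utils::write.csv(fits, paths[2], row.names = FALSE, na = "")
  utils::write.csv(feats, paths[3], row.names = FALSE, na = "")
  meta$gndfit_version <- as.character(utils::packageVersion("gndfit"))
  meta_path <- file.path(tmp, "meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  out <- run_python(python_helper("sqlite_bridge.py"),
                    c("write", path, meta_path, paths))
  invisible(as.integer(out[length(out)]))
}

#' Read an event store back
#'
#' @param path SQLite file written by [store_events()].
#' @return A list with `detections`, `fits`, `features` (data frames
#'   ordered by `event_id`) and `meta` (named list). A schema version
#'   other than the one this package writes is an error.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tmp <- tempfile("gndfit-read-")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  run_python(python_helper("sqlite_bridge.py"), c("read", path, tmp))
  read1 <- function(name) {
    d <- utils::read.csv(file.path(tmp, paste0(name, ".csv")))
    d
  }
  det <- read1("detections")
  fits <- read1("fits")
  feats <- read1("features")
  if (nrow(fits)) fits$converged <- as.logical(fits$converged)
  if (nrow(feats)) {
    feats$loc_valid <- as.logical(feats$loc_valid)
    feats$overlap_valid <- as.logical(feats$overlap_valid)
  }
  meta <- jsonlite::read_json(file.path(tmp, "meta.json"),
                              simplifyVector = TRUE)
  list(detections = det, fits = fits, features = feats, meta = meta)
}

#' Export an event store to a flat CSV
#'
#' Joins the three tables on `event_id` and writes one row per event
#' with all feature columns.
#'
#' @param path SQLite store path.
#' @param out Output CSV path.
#' @return `out`, invisibly.
#' @export
export_events <- function(path, out) {
  db <- read_events(path)
  joined <- merge(merge(db$detections, db$fits, by = "event_id"),
                  db$features, by = "event_id")
  joined <- joined[order(joined$event_id), , drop = FALSE]
  utils::write.csv(joined, out, row.names = FALSE, na = "")
  invisible(out)
}
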