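#' Read a current trace from disk
#'
#' Supported formats:
#' * `csv` — either columns `time_s,current_pA` (the sampling frequency
#'   is derived from the time column, which must be uniform to 1e-6
#'   relative) or a single `current_pA` column preceded by a header
#'   comment line `# fs_hz=<value>`.
#' * `npy` — a 1-D float array with a JSON sidecar `<path>.json`
#'   holding `{"fs_hz": ..., "t0_s": ...}`; read through the bundled
#'   numpy helper.
#' * `abf` — Axon Binary Files are not supported by this build; a clear
#'   error names the conversion path. Other loaders are easy to add.
#'
#' @param path File path.
#' @param format `"auto"` (from the extension), `"csv"`, `"npy"` or
#'   `"abf"`.
#' @return A [nanopore_trace()].
#' @export
read_trace <- function(path, format = c("auto", "csv", "npy", "abf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", npy = "npy", abf = "abf",
                     stop("cannot infer format from extension: ", path,
                          call. = FALSE))
  switch(format,
         csv = read_trace_csv(path),
         npy = read_trace_npy(path),
         abf = stop("ABF reading requires an Axon Binary File parser, ",
                    "which is not bundled; convert the recording to CSV ",
                    "(columns time_s,current_pA) first", call. = FALSE))
}

read_trace_csv <- function(path) {
  head_lines <- readLines(path, n = 5L)
  fs_line <- grep("^#\\s*fs_hz\\s*=", head_lines, value = TRUE)
  d <- utils::read.csv(path, comment.char = "#")
  if (length(fs_line)) {
    fs <- as.numeric(sub("^#\\s*fs_hz\\s*=\\s*", "", fs_line[1]))
    if (!is.finite(fs))
      stop("malformed fs_hz header in ", path, call. = FALSE)
    col <- if ("current_pA" %in% names(d)) d$current_pA else d[[1]]
    return(nanopore_trace(col, fs))
  }
  if (!all(c("time_s", "current_pA") %in% names(d)))
    stop("CSV trace needs columns time_s,current_pA or a '# fs_hz=' ",
         "header line", call. = FALSE)
  dt <- diff(d$time_s)
  if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
    stop("time column is not uniformly sampled", call. = FALSE)
  nanopore_trace(d$current_pA, fs = 1 / dt[1], t0 = d$time_s[1])
}

#' Write a trace to disk
#'
#' CSV traces are written with a `# fs_hz=` header comment and a single
#' `current_pA` column (compact, round-trips to 1e-6 pA); NPY traces
#' are written through the bundled numpy helper with a JSON sidecar and
#' round-trip bit-exactly.
#'
#' @param trace A [nanopore_trace()].
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"npy"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("auto", "csv", "npy")) {
  stopifnot(inherits(trace, "nanopore_trace"))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", npy = "npy",
                     stop("cannot infer format from extension: ", path,
                          call. = FALSE))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs_hz=%.10g", trace$fs), con)
    writeLines("current_pA", con)
    writeLines(formatC(trace$current, format = "g", digits = 12), con)
  } else {
    write_trace_npy(trace, path)
  }
  invisible(path)
}

python_helper <- function(name) {
  p <- system.file("python", name, package = "gndfit")
  if (p == "") stop("bundled python helper not found: ", name, call. = FALSE)
  p
}

run_python <- function(script, args) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "")
    stop("a python interpreter is required for this format/store but ",
         "none was found on PATH", call. = FALSE)
  out <- suppressWarnings(
    system2(py, c(script, args), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python helper failed: ", paste(out, collapse = "\n"),
         call. = FALSE)
  out
}

read_trace_npy <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("NPY trace requires a JSON sidecar ", sidecar,
         " with field fs_hz", call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs_hz))
    stop("sidecar ", sidecar, " is missing the required field fs_hz",
         call. = FALSE)
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  run_python(python_helper("npy_bridge.py"), c("tobin", path, tmp))
  x <- readBin(tmp, "double", n = file.info(tmp)$size / 8, size = 8,
               endian = "little")
  nanopore_trace(x, fs = meta$fs_hz,
                 t0 = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}

write_trace_npy <- function(trace, path) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  writeBin(trace$current, tmp, size = 8, endian = "little")
  run_python(python_helper("npy_bridge.py"), c("frombin", tmp, path))
  jsonlite::write_json(list(fs_hz = trace$fs, t0_s = trace$t0),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
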