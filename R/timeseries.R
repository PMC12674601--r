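#' Uniformly sampled time series
#'
#' The basic container for a single-channel recording: a local field
#' potential trace, a simulated membrane voltage, or any other uniformly
#' sampled real signal.
#'
#' @param samples numeric vector of samples (finite, length >= 1).
#' @param fs sampling rate in Hz (> 0).
#' @param units character label for the sample units (e.g. `"uV"`, `"mV"`).
#' @param t0 start time in seconds.
#' @return An object of class `"ca3_timeseries"`: a list with elements
#'   `samples`, `fs`, `units`, `t0`.
#' @examples
#' ts <- timeseries(sin(2 * pi * 6 * seq(0, 1, by = 1/1000)), fs = 1000)
#' ts_duration(ts)
#' @export
timeseries <- function(samples, fs, units = "a.u.", t0 = 0) {
  samples <- as.numeric(samples)
  fs <- as.numeric(fs)
  if (length(samples) < 1L) stop("timeseries needs at least one sample")
  if (!all(is.finite(samples))) stop("timeseries samples must be finite")
  if (!is.finite(fs) || fs <= 0) stop("sampling rate fs must be > 0")
  structure(list(samples = samples, fs = fs,
                 units = as.character(units), t0 = as.numeric(t0)),
            class = "ca3_timeseries")
}

#' @export
print.ca3_timeseries <- function(x, ...) {
  cat(sprintf("<timeseries> %d samples @ %g Hz (%.3f s), units=%s, t0=%g\n",
              length(x$samples), x$fs, ts_duration(x), x$units, x$t0))
  invisible(x)
}

#' Duration of a time series in seconds
#' @param ts a [timeseries()] object.
#' @return duration in seconds (n / fs).
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$fs

#' Time axis of a time series
#' @param ts a [timeseries()] object.
#' @return numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) ts$t0 + (seq_along(ts$samples) - 1) / ts$fs

#' Binary spike raster
#'
#' Cells-by-frames 0/1 matrix, e.g. action-potential rasters inferred from
#' calcium imaging.
#'
#' @param spikes binary matrix, one row per cell, one column per frame.
#' @param fs_frames frame rate in Hz (> 0).
#' @return An object of class `"ca3_raster"`.
#' @export
raster <- function(spikes, fs_frames) {
  spikes <- as.matrix(spikes)
  if (!all(spikes %in% c(0, 1))) stop("raster entries must be 0 or 1")
  if (!is.finite(fs_frames) || fs_frames <= 0) stop("fs_frames must be > 0")
  storage.mode(spikes) <- "integer"
  structure(list(spikes = spikes, fs_frames = fs_frames),
            class = "ca3_raster")
}

#' @export
print.ca3_raster <- function(x, ...) {
  cat(sprintf("<raster> %d cells x %d frames @ %g Hz (%d spikes)\n",
              nrow(x$spikes), ncol(x$spikes), x$fs_frames, sum(x$spikes)))
  invisible(x)
}

#' Split a recording into equal non-overlapping trials
#'
#' Consecutive windows of `trial_len` seconds; a trailing remainder shorter
#' than `trial_len` is discarded, so a 9.99 s record with `trial_len = 10`
#' yields an empty (zero-trial) set rather than an error.
#'
#' @param ts a [timeseries()] object.
#' @param trial_len trial duration in seconds (> 0).
#' @return An object of class `"ca3_trialset"`: list with `trials` (list of
#'   [timeseries()]), `trial_len`, `fs`.
#' @export
segment_trials <- function(ts, trial_len) {
  stopifnot(inherits(ts, "ca3_timeseries"))
  if (!is.finite(trial_len) || trial_len <= 0) stop("trial_len must be > 0")
  n_per <- floor(trial_len * ts$fs)
  n_tr <- floor(length(ts$samples) / n_per)
  trials <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    idx <- ((i - 1) * n_per + 1):(i * n_per)
    trials[[i]] <- timeseries(ts$samples[idx], ts$fs, ts$units,
                              t0 = ts$t0 + (i - 1) * n_per / ts$fs)
  }
  structure(list(trials = trials, trial_len = trial_len, fs = ts$fs),
            class = "ca3_trialset")
}

#' @export
print.ca3_trialset <- function(x, ...) {
  cat(sprintf("<trialset> %d trials of %g s @ %g Hz\n",
              length(x$trials), x$trial_len, x$fs))
  invisible(x)
}

## ---------------------------------------------------------------------
## I/O: '#'-header delimited text and a self-contained binary container.

parse_header <- function(lines) {
  hdr <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    kv <- strsplit(body, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) hdr[[trimws(kv[1])]] <- trimws(kv[2])
  }
  hdr
}

#' Read a time series from disk
#'
#' Two on-disk forms are supported. `"text"`: one sample per line, with
#' `#`-prefixed `key=value` header lines declaring at least `fs` (Hz) and
#' optionally `units` and `t0`. `"binary"`: the package's binary container
#' (JSON header + little-endian float64 payload), which round-trips
#' bit-exactly with [write_timeseries()].
#'
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @return A [timeseries()] object.
#' @export
read_timeseries <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "binary") return(read_ts_binary(path))
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- parse_header(lines[is_hdr])
  if (is.null(hdr$fs)) stop("format error: header must declare fs=<Hz>")
  fs <- suppressWarnings(as.numeric(hdr$fs))
  if (!is.finite(fs) || fs <= 0) stop("format error: invalid fs in header")
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(!is_hdr & nzchar(trimws(lines)))[which(is.na(vals))[1]]
    stop(sprintf("parse error: non-numeric sample at line %d", bad))
  }
  timeseries(vals, fs, hdr$units %||% "a.u.",
             as.numeric(hdr$t0 %||% 0))
}

#' Write a time series to disk
#'
#' @inheritParams read_timeseries
#' @param ts a [timeseries()] object.
#' @param digits significant digits for the text format.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, format = c("text", "binary"),
                             digits = 10) {
  stopifnot(inherits(ts, "ca3_timeseries"))
  format <- match.arg(format)
  if (format == "binary") return(write_ts_binary(ts, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", ts$fs),
               sprintf("# units=%s", ts$units),
               sprintf("# t0=%.10g", ts$t0),
               formatC(ts$samples, digits = digits, format = "g")), con)
  invisible(path)
}

TS_MAGIC <- charToRaw("CA3DYNTS")

write_ts_binary <- function(ts, path) {
  hdr <- jsonlite::toJSON(list(fs = ts$fs, units = ts$units, t0 = ts$t0,
                               n = length(ts$samples)), auto_unbox = TRUE)
  hraw <- charToRaw(as.character(hdr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(TS_MAGIC, con)
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  writeBin(ts$samples, con, size = 8, endian = "little")
  invisible(path)
}

read_ts_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", length(TS_MAGIC))
  if (!identical(magic, TS_MAGIC)) stop("format error: not a ca3dyn container")
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (is.null(hdr$fs) || hdr$fs <= 0) stop("format error: invalid header fs")
  samples <- readBin(con, "double", hdr$n, size = 8, endian = "little")
  timeseries(samples, hdr$fs, hdr$units %||% "a.u.", hdr$t0 %||% 0)
}

#' Read / write a spike raster as delimited text
#'
#' Cells x frames 0/1 matrix, tab-delimited, with a `# fs_frames=<Hz>`
#' header line.
#'
#' @param path file path.
#' @return [read_raster()] returns a [raster()] object.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- parse_header(lines[grepl("^#", lines)])
  if (is.null(hdr$fs_frames)) stop("format error: header must declare fs_frames")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  mat <- do.call(rbind, lapply(strsplit(body, "\t"), as.integer))
  raster(mat, as.numeric(hdr$fs_frames))
}

#' @rdname read_raster
#' @param r a [raster()] object.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "ca3_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_frames=%.10g", r$fs_frames), con)
  utils::write.table(r$spikes, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
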