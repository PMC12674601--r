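#' Event-detection configuration
#'
#' The sustained-run rule (a window of at least `sustained_win` seconds
#' whose RMS is at least `sustained_ratio` times the RMS of the
#' immediately preceding `sustained_win` seconds) is fixed by its
#' definition; the discharge and burst thresholds are conventional
#' in-vitro LFP defaults, fully configurable, and reported alongside
#' every output.
#'
#' @param sustained_win sustained-run minimum duration and baseline
#'   window (s), default 30.
#' @param sustained_ratio RMS ratio opening a sustained run, default 5.
#' @param discharge_threshold_sd discharge threshold in robust SDs of the
#'   record, default 6 (clears the Gaussian-noise tail over minutes-long
#'   records while leaving margin below events of 8x the baseline RMS).
#' @param duration_bounds named numeric (ms): `spike_max` (default 80),
#'   `sharp_max` (250), `ldd_min` (1000). Events between `sharp_max` and
#'   `ldd_min` are labelled `"other"`.
#' @param merge_gap_ms gap (ms) below which supra-threshold discharge
#'   segments are merged, default 100.
#' @param burst_env_sd burst threshold in SDs of the band envelope,
#'   default 6.
#' @param burst_min_cycles minimum burst duration in cycles of the band
#'   center frequency, default 3.
#' @return a `"detection_config"` list.
#' @export
detection_config <- function(sustained_win = 30, sustained_ratio = 5,
                             discharge_threshold_sd = 6,
                             duration_bounds = c(spike_max = 80,
                                                 sharp_max = 250,
                                                 ldd_min = 1000),
                             merge_gap_ms = 100,
                             burst_env_sd = 6, burst_min_cycles = 3) {
  if (any(c(sustained_win, sustained_ratio, discharge_threshold_sd,
            burst_env_sd, burst_min_cycles) <= 0))
    stop("all thresholds must be > 0")
  structure(list(sustained_win = sustained_win,
                 sustained_ratio = sustained_ratio,
                 discharge_threshold_sd = discharge_threshold_sd,
                 duration_bounds = duration_bounds,
                 merge_gap_ms = merge_gap_ms,
                 burst_env_sd = burst_env_sd,
                 burst_min_cycles = burst_min_cycles),
            class = "detection_config")
}

event_list <- function(events, record_duration) {
  if (nrow(events)) events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, record_duration = record_duration,
                 rate_per_1000s = 1000 * nrow(events) / record_duration),
            class = "ca3_eventlist")
}

#' @export
print.ca3_eventlist <- function(x, ...) {
  cat(sprintf("<events> %d events in %.1f s (%.2f per 1000 s)\n",
              nrow(x$events), x$record_duration, x$rate_per_1000s))
  if (nrow(x$events)) print(utils::head(x$events, 10))
  invisible(x)
}

## merge intervals (matrix with onset/offset columns) closer than gap
merge_intervals <- function(on, off, gap = 0) {
  if (!length(on)) return(cbind(onset = numeric(), offset = numeric()))
  o <- order(on); on <- on[o]; off <- off[o]
  res_on <- on[1]; res_off <- off[1]
  for (i in seq_along(on)[-1]) {
    if (on[i] <= res_off[length(res_off)] + gap) {
      res_off[length(res_off)] <- max(res_off[length(res_off)], off[i])
    } else {
      res_on <- c(res_on, on[i]); res_off <- c(res_off, off[i])
    }
  }
  cbind(onset = res_on, offset = res_off)
}

#' Detect sustained high-amplitude runs
#'
#' Per-second RMS is scanned (1 s hop); a run opens where the RMS reaches
#' `sustained_ratio` times the RMS of the `sustained_win` seconds
#' immediately preceding it (baseline frozen at run onset), extends while
#' the criterion holds, and counts only if it lasts at least
#' `sustained_win` seconds. Overlapping detections are merged.
#'
#' @param ts a [timeseries()] longer than `2 * sustained_win`.
#' @param cfg a [detection_config()].
#' @return a `"ca3_eventlist"` with class `"sustained"` events.
#' @export
detect_sustained_events <- function(ts, cfg = detection_config()) {
  stopifnot(inherits(ts, "ca3_timeseries"))
  dur <- ts_duration(ts)
  W <- cfg$sustained_win
  if (dur <= 2 * W) stop("record must be longer than ", 2 * W, " s")
  nsec <- floor(dur)
  ## per-second mean square
  sec_ms <- vapply(seq_len(nsec), function(i) {
    idx <- (round((i - 1) * ts$fs) + 1):min(length(ts$samples),
                                            round(i * ts$fs))
    mean(ts$samples[idx]^2)
  }, numeric(1))
  cs <- c(0, cumsum(sec_ms))
  base_rms <- function(i) sqrt((cs[i] - cs[i - W]) / W)  # RMS of [i-W, i)
  on <- numeric(); off <- numeric(); peak <- numeric()
  i <- W + 1
  while (i <= nsec) {
    b <- base_rms(i)
    if (b > 0 && sqrt(sec_ms[i]) >= cfg$sustained_ratio * b) {
      j <- i
      while (j < nsec && sqrt(sec_ms[j + 1]) >= cfg$sustained_ratio * b)
        j <- j + 1
      if (j - i + 1 >= W) {
        on <- c(on, i - 1); off <- c(off, j)
        peak <- c(peak, sqrt(max(sec_ms[i:j])))
      }
      i <- j + 1
    } else i <- i + 1
  }
  iv <- merge_intervals(on, off)
  ev <- data.frame(onset = iv[, 1], offset = iv[, 2],
                   class = rep("sustained", nrow(iv)),
                   peak = if (nrow(iv)) peak[seq_len(nrow(iv))] else numeric(),
                   band = rep("broadband", nrow(iv)))
  event_list(ev, dur)
}

#' Detect and classify epileptiform discharges
#'
#' Candidate events are regions where the absolute signal exceeds
#' `discharge_threshold_sd` robust SDs (1.4826 x MAD, immune to
#' contamination by the events themselves). Event extent is measured
#' with hysteresis — each detection is extended outward while the signal
#' stays above half the threshold — so a waveform's duration is not
#' underestimated to the few samples around its peak. Nearby segments
#' are merged (`merge_gap_ms`) and classified by duration: spike
#' (< `spike_max` ms), sharp wave (`spike_max`-`sharp_max` ms), LDD
#' (long-duration discharge, > `ldd_min` ms), `"other"` in between.
#'
#' @param ts a [timeseries()] of at least 60 s (baseline estimation).
#' @param cfg a [detection_config()].
#' @return a `"ca3_eventlist"`; per-class rates per 1000 s are in
#'   `attr(, "class_rates")`.
#' @export
detect_discharges <- function(ts, cfg = detection_config()) {
  stopifnot(inherits(ts, "ca3_timeseries"))
  dur <- ts_duration(ts)
  if (dur < 60) stop("record must be at least 60 s for baseline estimation")
  sd_r <- stats::mad(ts$samples)
  if (sd_r == 0) stop("degenerate baseline: flat signal")
  thr <- cfg$discharge_threshold_sd * sd_r
  hit <- abs(ts$samples) > thr
  if (!any(hit)) return(event_list(empty_events(), dur))
  ## hysteresis: keep the half-threshold runs that contain a full hit
  lo <- abs(ts$samples) > thr / 2
  r <- rle(lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  sel <- sel[vapply(sel, function(i) any(hit[starts[i]:ends[i]]),
                    logical(1))]
  if (!length(sel)) return(event_list(empty_events(), dur))
  iv <- merge_intervals((starts[sel] - 1) / ts$fs, ends[sel] / ts$fs,
                        gap = cfg$merge_gap_ms / 1000)
  dur_ms <- (iv[, 2] - iv[, 1]) * 1000
  db <- cfg$duration_bounds
  cls <- ifelse(dur_ms < db["spike_max"], "spike",
         ifelse(dur_ms <= db["sharp_max"], "sharp-wave",
         ifelse(dur_ms > db["ldd_min"], "LDD", "other")))
  pk <- vapply(seq_len(nrow(iv)), function(i) {
    idx <- (round(iv[i, 1] * ts$fs) + 1):round(iv[i, 2] * ts$fs)
    max(abs(ts$samples[idx]))
  }, numeric(1))
  ev <- data.frame(onset = iv[, 1], offset = iv[, 2], class = cls,
                   peak = pk, band = "broadband")
  out <- event_list(ev, dur)
  attr(out, "class_rates") <-
    1000 * table(factor(cls, c("spike", "sharp-wave", "LDD", "other"))) / dur
  out
}

empty_events <- function() {
  data.frame(onset = numeric(), offset = numeric(), class = character(),
             peak = numeric(), band = character())
}

#' Detect oscillatory bursts in a frequency band
#'
#' Band-passes the signal (e.g. low gamma 30-80 Hz, high gamma/ripple
#' 80-160 Hz), extracts the Hilbert envelope, and marks bursts where the
#' envelope exceeds `burst_env_sd` envelope SDs for at least
#' `burst_min_cycles` cycles of the band center frequency. Detections
#' confined to the first or last few cycles of the record are discarded:
#' filter and Hilbert edge transients concentrate there.
#'
#' @param ts a [timeseries()].
#' @param band numeric length-2 (Hz), within Nyquist.
#' @param cfg a [detection_config()].
#' @return a `"ca3_eventlist"` labelled with the band.
#' @export
detect_band_bursts <- function(ts, band, cfg = detection_config()) {
  stopifnot(inherits(ts, "ca3_timeseries"))
  filt <- bandpass(ts, band[1], band[2])
  env <- analytic_amplitude_phase(filt)$amplitude$samples
  thr <- cfg$burst_env_sd * stats::sd(env)
  f_center <- mean(band)
  min_dur <- cfg$burst_min_cycles / f_center
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  sel <- which(r$values)
  on <- (starts[sel] - 1) / ts$fs; off <- ends[sel] / ts$fs
  iv <- merge_intervals(on, off, gap = min_dur / 2)
  keep <- (iv[, 2] - iv[, 1]) >= min_dur
  ## drop edge-transient detections (filter/Hilbert settling regions)
  margin <- 3 / band[1]
  keep <- keep & iv[, 2] > margin & iv[, 1] < ts_duration(ts) - margin
  iv <- iv[keep, , drop = FALSE]
  pk <- vapply(seq_len(nrow(iv)), function(i) {
    idx <- (round(iv[i, 1] * ts$fs) + 1):round(iv[i, 2] * ts$fs)
    max(env[idx])
  }, numeric(1))
  band_lab <- sprintf("%g-%g Hz", band[1], band[2])
  ev <- data.frame(onset = iv[, 1], offset = iv[, 2],
                   class = rep("burst", nrow(iv)), peak = pk,
                   band = rep(band_lab, nrow(iv)))
  event_list(ev, ts_duration(ts))
}

#' Population synchrony of a calcium raster
#'
#' The fraction of cells simultaneously active in each frame, and the
#' synchronous events: local maxima of that fraction above
#' `event_threshold` (ties within a plateau resolved to its first
#' frame).
#'
#' @param r a [raster()] with at least 2 cells.
#' @param event_threshold minimum active fraction for a sync event.
#' @return An object of class `"ca3_synchrony"`: list with
#'   `active_fraction` (per frame), `sync_events` (data frame of frame,
#'   time, amplitude), `fs_frames`.
#' @export
calcium_synchrony <- function(r, event_threshold = 0.3) {
  stopifnot(inherits(r, "ca3_raster"))
  if (nrow(r$spikes) < 2) stop("need at least 2 cells")
  frac <- colMeans(r$spikes)
  n <- length(frac)
  peaks <- integer()
  i <- 1
  while (i <= n) {
    if (frac[i] > event_threshold) {
      ## extend over the plateau of equal values
      j <- i
      while (j < n && frac[j + 1] == frac[i]) j <- j + 1
      left_ok <- i == 1 || frac[i - 1] < frac[i]
      right_ok <- j == n || frac[j + 1] < frac[i]
      if (left_ok && right_ok) peaks <- c(peaks, i)  # first frame of plateau
      i <- j + 1
    } else i <- i + 1
  }
  structure(list(active_fraction = frac,
                 sync_events = data.frame(frame = peaks,
                                          time = (peaks - 1) / r$fs_frames,
                                          amplitude = frac[peaks]),
                 fs_frames = r$fs_frames),
            class = "ca3_synchrony")
}

#' @export
print.ca3_synchrony <- function(x, ...) {
  cat(sprintf("<synchrony> %d frames, %d sync events, max fraction %.2f\n",
              length(x$active_fraction), nrow(x$sync_events),
              max(x$active_fraction)))
  invisible(x)
}
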