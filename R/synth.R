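#' Configuration for the phase-amplitude-coupled signal generator
#'
#' Describes a theta carrier with one or more gamma components whose
#' amplitudes are modulated by theta phase, with a controllable preferred
#' phase per gamma frequency, per-cycle phase jitter, and additive white
#' noise. Ground truth is known exactly, so the modulogram and
#' monophasicity pipeline can be tested end to end.
#'
#' @param theta_f theta frequency (Hz).
#' @param amp_freqs gamma component frequencies (Hz).
#' @param coupling_depth modulation depth in `[0, 1]` (0 = no coupling).
#' @param preferred_phase preferred theta phase (rad) per gamma frequency
#'   (recycled); gamma amplitude is maximal at this phase.
#' @param phase_jitter_sd SD (rad) of a per-theta-cycle random offset added
#'   to the preferred phase.
#' @param noise_sd additive white-noise SD (signal units).
#' @param duration record length (s).
#' @param fs sampling rate (Hz); must exceed `2 * max(amp_freqs)`.
#' @param seed integer RNG seed.
#' @param theta_amp,gamma_amp carrier and gamma component amplitudes.
#' @return a `"pac_gen_config"` list.
#' @export
pac_gen_config <- function(theta_f = 6, amp_freqs = seq(30, 100, by = 10),
                           coupling_depth = 0.9, preferred_phase = 0,
                           phase_jitter_sd = 0, noise_sd = 0.1,
                           duration = 30, fs = 1000, seed = 1,
                           theta_amp = 1, gamma_amp = 0.25) {
  if (coupling_depth < 0 || coupling_depth > 1)
    stop("coupling_depth must be in [0, 1]")
  if (fs <= 2 * max(amp_freqs)) stop("fs must exceed 2 * max(amp_freqs)")
  structure(list(theta_f = theta_f, amp_freqs = amp_freqs,
                 coupling_depth = coupling_depth,
                 preferred_phase = rep_len(preferred_phase, length(amp_freqs)),
                 phase_jitter_sd = phase_jitter_sd, noise_sd = noise_sd,
                 duration = duration, fs = fs, seed = as.integer(seed),
                 theta_amp = theta_amp, gamma_amp = gamma_amp),
            class = "pac_gen_config")
}

#' Generate a phase-amplitude-coupled test signal
#'
#' `signal = theta carrier + sum_f gamma_f * (1 + depth * cos(theta phase -
#' preferred phase + jitter)) + white noise`. Deterministic given the
#' config seed.
#'
#' @param cfg a [pac_gen_config()].
#' @return list with `ts` (a [timeseries()]) and `truth` (data frame of
#'   per-frequency preferred phase).
#' @export
gen_pac_signal <- function(cfg) {
  stopifnot(inherits(cfg, "pac_gen_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  n <- round(cfg$duration * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  theta_phase <- 2 * pi * cfg$theta_f * t
  x <- cfg$theta_amp * cos(theta_phase)
  ## per-theta-cycle jitter: piecewise-constant random phase offset
  cyc <- floor(theta_phase / (2 * pi)) + 1L
  n_cyc <- max(cyc)
  jit <- if (cfg$phase_jitter_sd > 0)
    stats::rnorm(n_cyc, 0, cfg$phase_jitter_sd) else numeric(n_cyc)
  jit_t <- jit[cyc]
  for (i in seq_along(cfg$amp_freqs)) {
    f <- cfg$amp_freqs[i]
    rho <- stats::runif(1, 0, 2 * pi)
    env <- 1 + cfg$coupling_depth *
      cos(theta_phase - cfg$preferred_phase[i] + jit_t)
    x <- x + cfg$gamma_amp * env * cos(2 * pi * f * t + rho)
  }
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  list(ts = timeseries(x, cfg$fs, "a.u."),
       truth = data.frame(freq = cfg$amp_freqs,
                          preferred_phase = cfg$preferred_phase))
}

#' Benchmark series with known dynamical character
#'
#' Ground-truth stand-ins for chaotic versus periodic dynamics, used to
#' validate the 0-1 chaos test: the logistic map, the skew-tent map, a
#' sampled sinusoid, and a Gaussian AR(1) process.
#'
#' @param kind one of `"logistic"`, `"skew-tent"`, `"sine"`, `"ar1"`.
#' @param n number of samples (>= 1000 recommended for test use).
#' @param params named list of map parameters: logistic `r`, `x0`;
#'   skew-tent `a`, `x0`; sine `f`, `fs`, `amp`; ar1 `phi`, `sd`.
#' @param seed integer seed (used by `ar1` only).
#' @return numeric vector of length `n`.
#' @examples
#' gen_chaos_benchmark("logistic", 3, list(r = 4, x0 = 0.2))
#' @export
gen_chaos_benchmark <- function(kind, n, params = list(), seed = 1) {
  kind <- as.character(kind)
  n <- as.integer(n)
  if (kind == "logistic") {
    r <- params$r %||% 4; x <- numeric(n); x[1] <- params$x0 %||% 0.2
    for (i in seq_len(n - 1)) x[i + 1] <- r * x[i] * (1 - x[i])
    x
  } else if (kind == "skew-tent") {
    a <- params$a %||% 0.63; x <- numeric(n); x[1] <- params$x0 %||% 0.3
    for (i in seq_len(n - 1))
      x[i + 1] <- if (x[i] < a) x[i] / a else (1 - x[i]) / (1 - a)
    x
  } else if (kind == "sine") {
    f <- params$f %||% 1; fs <- params$fs %||% 8; amp <- params$amp %||% 1
    amp * sin(2 * pi * f * (seq_len(n) - 1) / fs)
  } else if (kind == "ar1") {
    phi <- params$phi %||% 0.9; s <- params$sd %||% 1
    set.seed(derive_seed(seed, 2L))
    as.numeric(stats::filter(stats::rnorm(n, 0, s), phi,
                             method = "recursive"))
  } else stop("unknown benchmark kind: ", kind)
}

#' Configuration for the event-seeded LFP generator
#'
#' @param base_noise_rms RMS of the Gaussian background (signal units).
#' @param events data frame with columns `onset` (s), `duration` (s),
#'   `class` (one of `"spike"`, `"sharp-wave"`, `"LDD"`,
#'   `"sustained-run"`, `"gamma-burst"`, `"ripple-burst"`), `amplitude`
#'   (multiplier of the baseline RMS).
#' @param fs sampling rate (Hz).
#' @param duration record length (s).
#' @param seed integer seed.
#' @return an `"event_gen_config"` list.
#' @export
event_gen_config <- function(base_noise_rms = 1, events = NULL, fs = 1000,
                             duration = 120, seed = 1) {
  if (is.null(events))
    events <- data.frame(onset = numeric(), duration = numeric(),
                         class = character(), amplitude = numeric())
  stopifnot(all(c("onset", "duration", "class", "amplitude") %in%
                  names(events)))
  if (any(events$onset < 0 | events$onset + events$duration > duration))
    stop("config error: events must lie within the record")
  for (cl in unique(events$class)) {
    e <- events[events$class == cl, , drop = FALSE]
    e <- e[order(e$onset), , drop = FALSE]
    if (nrow(e) > 1 &&
        any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)]))
      stop("config error: overlapping events within class ", cl)
  }
  structure(list(base_noise_rms = base_noise_rms, events = events,
                 fs = fs, duration = duration, seed = as.integer(seed)),
            class = "event_gen_config")
}

#' Generate an LFP with implanted events of known class and timing
#'
#' Background Gaussian noise at `base_noise_rms`, plus per-event
#' waveforms: `"spike"` a brief Gaussian-windowed deflection;
#' `"sharp-wave"` a half-sine deflection; `"LDD"` an edge-tapered
#' high-amplitude 4 Hz rhythmic discharge (band-limited, so it does not
#' masquerade as gamma/ripple content); `"sustained-run"` scales the
#' background RMS by the amplitude multiplier for the event duration;
#' `"gamma-burst"` and `"ripple-burst"` are Hann-windowed wave packets
#' at 55 and 120 Hz respectively.
#'
#' @param cfg an [event_gen_config()].
#' @return list with `ts` (a [timeseries()]) and `truth` (the ground-truth
#'   event table).
#' @export
gen_lfp_with_events <- function(cfg) {
  stopifnot(inherits(cfg, "event_gen_config"))
  set.seed(derive_seed(cfg$seed, 3L))
  n <- round(cfg$duration * cfg$fs)
  x <- stats::rnorm(n, 0, cfg$base_noise_rms)
  ev <- cfg$events
  for (i in seq_len(nrow(ev))) {
    i0 <- max(1L, round(ev$onset[i] * cfg$fs) + 1L)
    i1 <- min(n, round((ev$onset[i] + ev$duration[i]) * cfg$fs))
    idx <- i0:i1
    m <- length(idx)
    amp <- ev$amplitude[i] * cfg$base_noise_rms
    cl <- ev$class[i]
    if (cl == "sustained-run") {
      x[idx] <- x[idx] * ev$amplitude[i]
    } else if (cl == "LDD") {
      ## Tukey taper: full amplitude over the central 80% of the event
      ramp <- max(2L, round(0.1 * m))
      w <- rep(1, m)
      w[1:ramp] <- 0.5 - 0.5 * cos(pi * (1:ramp) / ramp)
      w[m:(m - ramp + 1)] <- w[1:ramp]
      x[idx] <- x[idx] + amp * w * sin(2 * pi * 4 * (idx - i0) / cfg$fs)
    } else if (cl == "spike") {
      tt <- seq_len(m) - m / 2
      x[idx] <- x[idx] + amp * exp(-tt^2 / (2 * (m / 6)^2))
    } else if (cl == "sharp-wave") {
      x[idx] <- x[idx] + amp * sin(pi * seq_len(m) / m)
    } else if (cl %in% c("gamma-burst", "ripple-burst")) {
      f0 <- if (cl == "gamma-burst") 55 else 120
      w <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
      x[idx] <- x[idx] + amp * w * cos(2 * pi * f0 * (idx - i0) / cfg$fs)
    } else stop("unknown event class: ", cl)
  }
  list(ts = timeseries(x, cfg$fs, "a.u."), truth = ev)
}

#' Configuration for the synthetic raster generator
#'
#' @param n_cells number of cells.
#' @param fs_frames frame rate (Hz), e.g. 31 for two-photon calcium data.
#' @param duration record length (s).
#' @param base_rate per-cell background firing rate (Hz); must be below
#'   `fs_frames`.
#' @param sync_event_rate rate of network-wide synchronous events (Hz).
#' @param sync_fraction fraction of cells recruited per sync event.
#' @param regime `"poisson"`, `"periodic"` or `"sync-bursts"`.
#' @param seed integer seed.
#' @return a `"raster_gen_config"` list.
#' @export
raster_gen_config <- function(n_cells = 100, fs_frames = 31, duration = 60,
                              base_rate = 0.5, sync_event_rate = 0,
                              sync_fraction = 0.8,
                              regime = c("poisson", "periodic", "sync-bursts"),
                              seed = 1) {
  regime <- match.arg(regime)
  if (base_rate < 0 || sync_event_rate < 0) stop("rates must be >= 0")
  if (base_rate >= fs_frames)
    stop("config error: base_rate must be below the frame rate")
  if (sync_fraction < 0 || sync_fraction > 1)
    stop("sync_fraction must be in [0, 1]")
  structure(list(n_cells = n_cells, fs_frames = fs_frames,
                 duration = duration, base_rate = base_rate,
                 sync_event_rate = sync_event_rate,
                 sync_fraction = sync_fraction, regime = regime,
                 seed = as.integer(seed)),
            class = "raster_gen_config")
}

#' Generate a spike raster with known synchrony structure
#'
#' `"poisson"`: i.i.d. Bernoulli(`base_rate / fs_frames`) per cell and
#' frame. `"periodic"`: every cell fires every `round(fs_frames /
#' base_rate)` frames. `"sync-bursts"`: Poisson background plus sync
#' events at which `sync_fraction` of the cells fire in the same frame.
#'
#' @param cfg a [raster_gen_config()].
#' @return list with `r` (a [raster()]) and `sync_frames` (ground-truth
#'   frame indices of sync events; empty unless regime is
#'   `"sync-bursts"`).
#' @export
gen_raster <- function(cfg) {
  stopifnot(inherits(cfg, "raster_gen_config"))
  set.seed(derive_seed(cfg$seed, 4L))
  n_fr <- round(cfg$duration * cfg$fs_frames)
  p <- cfg$base_rate / cfg$fs_frames
  sync_frames <- integer()
  if (cfg$regime == "periodic") {
    spk <- matrix(0L, cfg$n_cells, n_fr)
    if (cfg$base_rate > 0) {
      period <- max(1L, round(cfg$fs_frames / cfg$base_rate))
      spk[, seq(period, n_fr, by = period)] <- 1L
    }
  } else {
    spk <- matrix(stats::rbinom(cfg$n_cells * n_fr, 1L, p),
                  cfg$n_cells, n_fr)
    if (cfg$regime == "sync-bursts") {
      n_ev <- round(cfg$sync_event_rate * cfg$duration)
      if (n_ev > 0) {
        sync_frames <- sort(sample.int(n_fr, n_ev))
        n_rec <- round(cfg$sync_fraction * cfg$n_cells)
        for (fr in sync_frames)
          spk[sample.int(cfg$n_cells, n_rec), fr] <- 1L
      }
    }
  }
  list(r = raster(spk, cfg$fs_frames), sync_frames = sync_frames)
}
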