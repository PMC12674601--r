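#' Configuration for the noise-robust 0-1 chaos test
#'
#' @param sigma amplitude of the additive noise term in the mean square
#'   displacement (default 0.5); the noise is uniform on `[-1/2, 1/2]`.
#' @param n_c number of random rotation constants c (default 100).
#' @param c_range interval the constants are drawn from, default
#'   `(0, 2*pi)`.
#' @param msd_fraction maximum displacement lag as a fraction of the
#'   series length (default 0.1, standard bias control for MSD
#'   estimates); must be in `(0, 0.5]`.
#' @param downsample_to effective sampling rate (Hz) for oversampled
#'   signals before the test (default 50; the test assumes coarse
#'   sampling relative to the signal dynamics).
#' @param seed integer seed for the c draws and the noise term.
#' @return a `"chaos_config"` list.
#' @export
chaos_config <- function(sigma = 0.5, n_c = 100, c_range = c(0, 2 * pi),
                         msd_fraction = 0.1, downsample_to = 50,
                         seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_c < 1) stop("n_c must be >= 1")
  if (msd_fraction <= 0 || msd_fraction > 0.5)
    stop("msd_fraction must be in (0, 0.5]")
  structure(list(sigma = sigma, n_c = as.integer(n_c), c_range = c_range,
                 msd_fraction = msd_fraction,
                 downsample_to = downsample_to, seed = as.integer(seed)),
            class = "chaos_config")
}

## Mean square displacement of the (p, q) trajectory for one rotation
## constant, over lags 1..n_max. The printed estimator sums j over the
## record; lags beyond the record are meaningless, so the mean is taken
## over the N - n valid pairs (the standard MSD estimator). Computed via
## FFT autocorrelation: sum_j x(j) x(j+n) for all n in O(N log N).
msd_pq <- function(x, n_max) {
  N <- length(x)
  nfft <- stats::nextn(2L * N, 2)
  X <- stats::fft(c(x, numeric(nfft - N)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE))[1:(n_max + 1)] / nfft
  cum2 <- cumsum(x^2)
  n <- seq_len(n_max)
  ((cum2[N] - cum2[n]) + cum2[N - n] - 2 * ac[n + 1]) / (N - n)
}

#' Noise-robust 0-1 test for chaos
#'
#' Drives the 2-D system `p(n+1) = p(n) + phi(n) cos(c n)`,
#' `q(n+1) = q(n) + phi(n) sin(c n)` with the series `phi`, computes the
#' time-averaged mean square displacement `M_c(n)` (plus an additive
#' noise term `sigma * eta_n`, `eta` uniform on `[-1/2, 1/2]`) for lags
#' up to `msd_fraction` of the series length, and correlates it with the
#' lag. The median of the correlation coefficient `K_c` over `n_c`
#' random draws of c is the statistic `K`: values approaching 1 indicate
#' chaos, values near 0 periodicity.
#'
#' @param series numeric vector (finite; length >= 1000 for reliable
#'   use).
#' @param cfg a [chaos_config()].
#' @return An object of class `"ca3_chaosresult"`: list with `K`
#'   (median), `K_per_c`, `c_values`.
#' @export
chaos_k_statistic <- function(series, cfg = chaos_config()) {
  stopifnot(inherits(cfg, "chaos_config"))
  series <- as.numeric(series)
  N <- length(series)
  if (N < 1000) stop("series must have at least 1000 samples")
  if (!all(is.finite(series))) stop("series must be finite")
  n_max <- max(10L, floor(cfg$msd_fraction * N))
  n <- seq_len(n_max)
  set.seed(derive_seed(cfg$seed, 5L))
  c_vals <- stats::runif(cfg$n_c, cfg$c_range[1], cfg$c_range[2])
  idx <- seq_len(N)
  K_per_c <- vapply(c_vals, function(cc) {
    p <- cumsum(series * cos(cc * idx))
    q <- cumsum(series * sin(cc * idx))
    Mc <- msd_pq(p, n_max) + msd_pq(q, n_max) +
      cfg$sigma * stats::runif(n_max, -0.5, 0.5)
    if (stats::sd(Mc) == 0) {
      if (cfg$sigma == 0)
        stop("degenerate correlation: constant displacement with sigma = 0")
      return(0)
    }
    stats::cor(n, Mc)
  }, numeric(1))
  structure(list(K = stats::median(K_per_c), K_per_c = K_per_c,
                 c_values = c_vals),
            class = "ca3_chaosresult")
}

#' @export
print.ca3_chaosresult <- function(x, ...) {
  cat(sprintf("<chaos> K = %.3f (median of %d c draws)\n",
              x$K, length(x$K_per_c)))
  invisible(x)
}

#' Theta-rhythm instability of an LFP
#'
#' Band-passes the recording to the theta band (3-10 Hz), downsamples to
#' `cfg$downsample_to` (LFPs at several kHz are far oversampled for the
#' 0-1 test), normalizes to unit RMS (so K is amplitude-invariant), and
#' applies [chaos_k_statistic()].
#'
#' @param ts a [timeseries()] with `fs > 20` Hz and at least 1000
#'   effective samples after downsampling.
#' @param cfg a [chaos_config()].
#' @param theta_band theta band (Hz).
#' @return a `"ca3_chaosresult"`.
#' @export
theta_instability <- function(ts, cfg = chaos_config(),
                              theta_band = c(3, 10)) {
  stopifnot(inherits(ts, "ca3_timeseries"))
  if (ts$fs <= 20) stop("fs must exceed 20 Hz")
  filt <- bandpass(ts, theta_band[1], theta_band[2])
  ds <- subsample_ts(filt, cfg$downsample_to)
  x <- ds$samples
  if (length(x) < 1000)
    stop("record too short: fewer than 1000 samples at ",
         cfg$downsample_to, " Hz")
  rms <- sqrt(mean(x^2))
  if (rms > 0) x <- x / rms
  chaos_k_statistic(x, cfg)
}

#' Spiking instability of a raster
#'
#' Collapses the raster to the per-frame population spike count (the
#' minimal-assumption scalar reduction) and applies
#' [chaos_k_statistic()] directly, as for calcium-imaging rasters.
#'
#' @param r a [raster()] with at least 1000 frames.
#' @param cfg a [chaos_config()].
#' @return a `"ca3_chaosresult"`.
#' @export
raster_instability <- function(r, cfg = chaos_config()) {
  stopifnot(inherits(r, "ca3_raster"))
  if (nrow(r$spikes) < 1) stop("raster must contain at least one cell")
  if (ncol(r$spikes) < 1000) stop("raster must have at least 1000 frames")
  chaos_k_statistic(colSums(r$spikes), cfg)
}

#' Stochastic largest Lyapunov exponent from twin runs
#'
#' Measures the divergence between two simulations that differ only in a
#' small initial perturbation while sharing the identical noise sequence.
#' The divergence is expressed on the amplitude scale,
#' `eps(t) = |Q1(t) - Q2(t)| / sqrt(eps_max)` with
#' `eps_max = (max Q1 - min Q2)^2`, so that `eps(t) = eps(0) exp(L t)`
#' recovers the conventional exponent; `cumulative = TRUE` replaces the
#' instantaneous difference with its running RMS. L is the least-squares
#' slope of `ln eps` over the fit window (samples with `eps = 0`
#' excluded): by default from the first sample exceeding `10 * eps(0)`
#' (transient skip) to the first exceeding 0.5 (saturation), the full
#' record when neither bound is reached. A positive L indicates
#' dynamical instability.
#'
#' @param run1,run2 numeric vectors or [timeseries()] of equal length.
#' @param dt sample spacing in seconds (taken from the time series when
#'   given); L is reported per second (per iteration for map data with
#'   `dt = 1`).
#' @param fit_window optional `c(t_start, t_end)` in the units of `dt`.
#' @param cumulative use the running-RMS divergence instead of the
#'   instantaneous one.
#' @return An object of class `"ca3_lyapunov"`: list with `lambda`,
#'   `divergence_trace`, `eps0`, `fit_window`, `no_divergence`.
#' @export
lyapunov_from_twin_runs <- function(run1, run2, dt = NULL,
                                    fit_window = NULL,
                                    cumulative = FALSE) {
  if (inherits(run1, "ca3_timeseries")) {
    dt <- dt %||% (1 / run1$fs); run1 <- run1$samples
  }
  if (inherits(run2, "ca3_timeseries")) run2 <- run2$samples
  if (is.null(dt)) stop("dt must be given for plain numeric input")
  if (length(run1) != length(run2)) stop("runs must have equal length")
  d2 <- (run1 - run2)^2
  if (all(d2 == 0)) {
    return(structure(list(lambda = NA_real_, divergence_trace = d2,
                          eps0 = 0, fit_window = c(NA, NA),
                          no_divergence = TRUE),
                     class = "ca3_lyapunov"))
  }
  eps_max <- (max(run1) - min(run2))^2
  if (eps_max <= 0) eps_max <- max(d2)
  eps <- if (cumulative)
    sqrt(cumsum(d2) / seq_along(d2) / eps_max)
  else sqrt(d2 / eps_max)
  t <- (seq_along(eps) - 1) * dt
  pos <- which(eps > 0)
  eps0 <- eps[pos[1]]
  if (is.null(fit_window)) {
    i_start <- which(eps > 10 * eps0)[1]
    if (is.na(i_start)) i_start <- pos[1]
    i_end <- which(eps > 0.5)[1]
    if (is.na(i_end) || i_end <= i_start + 5) i_end <- length(eps)
    fit_window <- c(t[i_start], t[i_end])
  }
  keep <- t >= fit_window[1] & t <= fit_window[2] & eps > 0
  if (sum(keep) < 3) stop("fit window contains fewer than 3 usable samples")
  lambda <- unname(stats::coef(stats::lm(log(eps[keep]) ~ t[keep]))[2])
  structure(list(lambda = lambda, divergence_trace = eps, eps0 = eps0,
                 fit_window = fit_window, no_divergence = FALSE),
            class = "ca3_lyapunov")
}

#' @export
print.ca3_lyapunov <- function(x, ...) {
  if (isTRUE(x$no_divergence)) cat("<lyapunov> no divergence (runs identical)\n")
  else cat(sprintf("<lyapunov> lambda = %.4g, fit window [%.3g, %.3g]\n",
                   x$lambda, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}
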