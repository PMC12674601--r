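#' Phase-amplitude coupling analysis configuration
#'
#' Theta band 3-10 Hz; amplitude frequencies spanning 25-115 Hz (5 Hz
#' step by default), each extracted in a band of `+/- amp_bandwidth` Hz
#' around its center (the bandwidth must exceed the theta rate to capture
#' the modulation sidebands); 18 phase bins spanning `[-pi, pi]`; 10-s
#' trials.
#'
#' @param theta_band numeric length-2, Hz.
#' @param amp_freqs amplitude-frequency centers, Hz.
#' @param amp_bandwidth half-bandwidth around each center, Hz.
#' @param n_phase_bins number of theta phase bins.
#' @param trial_len trial duration, s.
#' @param cor_method `"pearson"` (default) or `"spearman"` for the
#'   monophasicity row correlations.
#' @return a `"pac_config"` list.
#' @export
pac_config <- function(theta_band = c(3, 10),
                       amp_freqs = seq(25, 115, by = 5),
                       amp_bandwidth = 10, n_phase_bins = 18,
                       trial_len = 10,
                       cor_method = c("pearson", "spearman")) {
  stopifnot(length(theta_band) == 2, theta_band[1] < theta_band[2])
  if (any(amp_freqs <= theta_band[2]))
    stop("amplitude frequencies must lie above the theta band")
  structure(list(theta_band = theta_band, amp_freqs = amp_freqs,
                 amp_bandwidth = amp_bandwidth,
                 n_phase_bins = as.integer(n_phase_bins),
                 trial_len = trial_len,
                 cor_method = match.arg(cor_method)),
            class = "pac_config")
}

#' Theta-phase / gamma-amplitude modulogram
#'
#' For each amplitude frequency the signal is band-pass filtered and its
#' Hilbert envelope extracted; theta phase comes from the analytic signal
#' of the theta-band-filtered trace. Each row of the result is the mean
#' envelope per theta phase bin, normalized to sum to 1 — so the
#' modulogram is invariant to per-frequency gain.
#'
#' @param ts a [timeseries()]; any window of at least two theta cycles.
#' @param cfg a [pac_config()].
#' @return An object of class `"ca3_modulogram"`: list with `matrix`
#'   (amplitude frequency x phase bin), `freqs`, `bin_centers` (rad).
#' @export
compute_modulogram <- function(ts, cfg = pac_config()) {
  stopifnot(inherits(ts, "ca3_timeseries"))
  nyq <- ts$fs / 2
  if (any(cfg$amp_freqs >= nyq))
    stop("amplitude frequency at or above Nyquist")
  theta <- bandpass(ts, cfg$theta_band[1], cfg$theta_band[2])
  phase <- analytic_amplitude_phase(theta)$phase$samples
  brks <- seq(-pi, pi, length.out = cfg$n_phase_bins + 1)
  bin <- pmin(cfg$n_phase_bins,
              pmax(1L, findInterval(phase, brks, rightmost.closed = TRUE)))
  m <- matrix(0, length(cfg$amp_freqs), cfg$n_phase_bins)
  for (i in seq_along(cfg$amp_freqs)) {
    f <- cfg$amp_freqs[i]
    lo <- max(cfg$theta_band[2], f - cfg$amp_bandwidth)
    hi <- min(nyq * 0.99, f + cfg$amp_bandwidth)
    env <- analytic_amplitude_phase(bandpass(ts, lo, hi))$amplitude$samples
    mu <- vapply(seq_len(cfg$n_phase_bins),
                 function(b) mean(env[bin == b]), numeric(1))
    mu[!is.finite(mu)] <- 0
    s <- sum(mu)
    m[i, ] <- if (s > 0) mu / s else rep(1 / cfg$n_phase_bins,
                                         cfg$n_phase_bins)
  }
  structure(list(matrix = m, freqs = cfg$amp_freqs,
                 bin_centers = (head(brks, -1) + tail(brks, -1)) / 2),
            class = "ca3_modulogram")
}

#' @export
print.ca3_modulogram <- function(x, ...) {
  cat(sprintf("<modulogram> %d amplitude freqs x %d phase bins\n",
              length(x$freqs), length(x$bin_centers)))
  invisible(x)
}

#' Monophasicity of a modulogram
#'
#' Correlates every pair of distinct amplitude-frequency rows and returns
#' the median of the off-diagonal correlation coefficients: close to 1
#' when all gamma frequencies lock to one theta phase, near 0 when the
#' preferred phases are scattered. A zero-variance row contributes 0 to
#' its pairs (with a warning) instead of propagating NaN.
#'
#' @param m a `"ca3_modulogram"` (at least 2 amplitude frequencies).
#' @param method correlation type; defaults to Pearson.
#' @return a value in `[-1, 1]`.
#' @export
monophasicity <- function(m, method = c("pearson", "spearman")) {
  stopifnot(inherits(m, "ca3_modulogram"))
  method <- match.arg(method)
  nf <- nrow(m$matrix)
  if (nf < 2) stop("need at least 2 amplitude frequencies")
  flat <- apply(m$matrix, 1, stats::sd) == 0
  if (any(flat)) warning(sum(flat), " zero-variance modulogram row(s)")
  vals <- numeric(0)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    vals <- c(vals, if (flat[i] || flat[j]) 0 else
      stats::cor(m$matrix[i, ], m$matrix[j, ], method = method))
  }
  stats::median(vals)
}

#' Per-trial monophasicity of a recording
#'
#' Segments the recording into non-overlapping trials (default 10 s),
#' computes a modulogram and its monophasicity per trial, and reports the
#' median across trials as the overall value (mean-of-two-central
#' convention for even trial counts).
#'
#' @param ts a [timeseries()] of duration >= `cfg$trial_len`.
#' @param cfg a [pac_config()].
#' @return list with `per_trial` (numeric) and `overall` (median).
#' @export
monophasicity_of_recording <- function(ts, cfg = pac_config()) {
  trials <- segment_trials(ts, cfg$trial_len)
  if (length(trials$trials) == 0)
    stop("recording shorter than one trial (", cfg$trial_len, " s)")
  per <- vapply(trials$trials, function(tr)
    monophasicity(compute_modulogram(tr, cfg), method = cfg$cor_method),
    numeric(1))
  list(per_trial = per, overall = stats::median(per))
}

#' Kullback-Leibler modulation index per amplitude frequency
#'
#' Tort-style coupling strength: for each normalized row p of the
#' modulogram, `MI = (log(Nbins) + sum(p log p)) / log(Nbins)`, i.e. the
#' KL divergence from the uniform phase distribution, scaled to `[0, 1]`
#' (0 = no modulation, 1 = all amplitude in one phase bin).
#'
#' @param m a `"ca3_modulogram"`.
#' @return named numeric vector, one MI per amplitude frequency.
#' @export
coupling_strength <- function(m) {
  stopifnot(inherits(m, "ca3_modulogram"))
  nb <- ncol(m$matrix)
  mi <- apply(m$matrix, 1, function(p) {
    plogp <- ifelse(p > 0, p * log(p), 0)
    (log(nb) + sum(plogp)) / log(nb)
  })
  names(mi) <- m$freqs
  mi
}

#' Exact one-tailed paired signed-rank test
#'
#' Exact permutation p-value of the Wilcoxon signed-rank statistic over
#' all `2^n` sign assignments (suitable for small paired designs, n <=
#' 25), computed by the shift algorithm on the rank generating function.
#' Zero differences and tied absolute differences are refused: rerun with
#' `ties = "midrank"` to use mid-ranks (the p-value is then exact for the
#' realized rank vector).
#'
#' @param a,b paired samples of equal length.
#' @param alternative `"less"` (a < b) or `"greater"` (a > b).
#' @param ties `"error"` (default) or `"midrank"`.
#' @return the exact one-tailed p-value.
#' @examples
#' paired_exact_signed_rank(1:8, 2:9, "less") # 1/256
#' @export
paired_exact_signed_rank <- function(a, b,
                                     alternative = c("less", "greater"),
                                     ties = c("error", "midrank")) {
  alternative <- match.arg(alternative)
  ties <- match.arg(ties)
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 1) stop("empty input")
  if (n > 25) stop("exact enumeration supported for n <= 25")
  d <- a - b
  if (any(d == 0))
    stop("zero differences present; exact signed-rank is undefined ",
         "(drop them or use ties = 'midrank' after removal)")
  r <- rank(abs(d))
  if (ties == "error" && anyDuplicated(abs(d)))
    stop("tied absolute differences; use ties = 'midrank'")
  ## W+ = sum of ranks of positive differences; "less" means a < b,
  ## i.e. mostly negative d, i.e. small W+.
  w_obs <- sum(r[d > 0])
  ## distribution of W+ under the null via the generating function
  ## prod_i (1 + z^{r_i}) / 2^n; mid-ranks are doubled to stay integral.
  scale <- 2L
  ri <- round(r * scale)
  dist <- numeric(sum(ri) + 1)  # index k+1 holds count of W+*scale == k
  dist[1] <- 1
  for (k in ri) {
    shifted <- c(numeric(k), dist[seq_len(length(dist) - k)])
    dist <- dist + shifted
  }
  total <- 2^n
  w_scaled <- round(w_obs * scale)
  p_le <- sum(dist[seq_len(w_scaled + 1)]) / total
  p_ge <- sum(dist[(w_scaled + 1):length(dist)]) / total
  if (alternative == "less") p_le else p_ge
}
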