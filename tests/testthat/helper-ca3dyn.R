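## shared fixtures and independent oracles

sine_ts <- function(f, fs = 1000, dur = 10, amp = 1, phase = 0) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  timeseries(amp * cos(2 * pi * f * t + phase), fs)
}

## Independent reference implementation of the noise-robust 0-1 test:
## direct per-lag loops, no FFT, own RNG stream. Used only as an oracle.
ref_chaos_K <- function(series, sigma = 0.5, n_c = 100,
                        msd_fraction = 0.1, seed = 1) {
  set.seed(seed + 7777)
  N <- length(series)
  n_max <- max(10L, floor(msd_fraction * N))
  n <- seq_len(n_max)
  idx <- seq_len(N)
  cs <- stats::runif(n_c, 0, 2 * pi)
  Ks <- vapply(cs, function(cc) {
    p <- cumsum(series * cos(cc * idx))
    q <- cumsum(series * sin(cc * idx))
    M <- vapply(n, function(k)
      mean((p[(k + 1):N] - p[1:(N - k)])^2 +
             (q[(k + 1):N] - q[1:(N - k)])^2), numeric(1)) +
      sigma * stats::runif(n_max, -0.5, 0.5)
    stats::cor(n, M)
  }, numeric(1))
  stats::median(Ks)
}

## Brute-force exact signed-rank p over all 2^n sign patterns.
brute_signed_rank_p <- function(a, b, alternative = "less") {
  d <- a - b
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- vapply(seq_len(2^n) - 1, function(code) {
    signs <- bitwAnd(bitwShiftR(code, seq_len(n) - 1), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  if (alternative == "less") mean(w_all <= w_obs) else mean(w_all >= w_obs)
}

## Literal scalar transcription of the O-LM current-balance equation and
## gating kinetics, kept deliberately separate from the package's code
## path (double-entry bookkeeping oracle).
olm_rhs_transcription <- function(V, gates, p, I_app = 0, I_syn = 0) {
  m <- gates["m"]; h <- gates["h"]; n <- gates["n"]; mp <- gates["mp"]
  a <- gates["a"]; b <- gates["b"]; r <- gates["r"]
  INa <- p["gNa"] * m^3 * h * (V - p["ENa"])
  INaP <- p["gNaP"] * mp * (V - p["ENa"])
  IK <- p["gK"] * n^4 * (V - p["EK"])
  IL <- p["gL"] * (V - p["EL"])
  Ih <- p["gh"] * r * (V - p["Eh"])
  IA <- p["gA"] * a * b * (V - p["EA"])
  unname((I_app - INa - INaP - IK - IL - Ih - IA - I_syn) / p["C"])
}

olm_gate_kin_transcription <- function(V, gate, v50 = -80) {
  if (gate == "m") {
    al <- -0.1 * (V + 38) / (exp(-0.1 * (V + 38)) - 1)
    be <- 4 * exp(-(V + 65) / 18)
  } else if (gate == "h") {
    al <- 0.07 * exp(-(V + 63) / 20)
    be <- 1 / (1 + exp(-(V + 33) / 10))
  } else if (gate == "n") {
    al <- 0.018 * (V - 25) / (1 - exp(-(V - 25) / 25))
    be <- 0.0036 * (V - 35) / (exp((V - 35) / 12) - 1)
  } else if (gate == "mp") {
    return(c(inf = 1 / (1 + exp(-(V + 52.3) / 6.8)), tau = 1))
  } else if (gate == "a") {
    return(c(inf = 1 / (1 + exp(-(V + 14) / 16.6)), tau = 5))
  } else if (gate == "b") {
    tau <- 1 / (0.000009 / exp((V - 26) / 18.5) +
                  0.014 / (0.2 + exp(-(V + 70) / 11)))
    return(c(inf = 1 / (1 + exp((V + 71) / 7.3)), tau = tau))
  } else if (gate == "r") {
    tau <- 1 / (exp(-14.59 - 0.086 * V) + exp(-1.87 + 0.0701 * V))
    return(c(inf = 1 / (1 + exp((V - v50) / 10.2)), tau = tau))
  } else stop("bad gate")
  tau <- 1 / (al + be)
  c(inf = al * tau, tau = tau)
}

## small circuit used across simulator tests (fast, theta-gamma capable)
small_circuit <- function(duration = 10, ...) {
  circuit_config(counts = c(3, 2, 3), dt = 0.05, duration = duration, ...)
}
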