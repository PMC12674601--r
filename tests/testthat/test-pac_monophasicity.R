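test_that("modulogram rows are normalized and reflect coupling structure", {
  cfg <- pac_config(amp_freqs = seq(35, 95, by = 15))
  ## locked coupling: every row's argmax bin contains phase 0; gamma
  ## components separated beyond the analysis bandwidth so no band sees
  ## a beat between neighbouring components
  cfg_sep <- pac_config(amp_freqs = c(40, 70, 100))
  g <- gen_pac_signal(pac_gen_config(duration = 10, seed = 1,
                                     amp_freqs = c(40, 70, 100),
                                     coupling_depth = 0.9))
  m <- compute_modulogram(g$ts, cfg_sep)
  expect_true(all(abs(rowSums(m$matrix) - 1) < 1e-10))
  expect_true(all(m$matrix >= 0))
  argmax_phase <- m$bin_centers[apply(m$matrix, 1, which.max)]
  expect_true(all(abs(argmax_phase) < pi / 9))
  ## no coupling: rows near uniform
  g0 <- gen_pac_signal(pac_gen_config(duration = 10, seed = 2,
                                      coupling_depth = 0))
  m0 <- compute_modulogram(g0$ts, cfg)
  expect_lt(max(abs(m0$matrix - 1 / 18)), 0.02)
  ## constant-amplitude gamma on a theta carrier (plus a noise floor so
  ## empty bands are not dominated by filter leakage): rows uniform
  set.seed(13)
  t <- (0:9999) / 1000
  x <- timeseries(cos(2 * pi * 6 * t) + 0.3 * cos(2 * pi * 47 * t) +
                    rnorm(length(t), 0, 0.05), 1000)
  mu <- compute_modulogram(x, cfg)
  expect_lt(max(abs(mu$matrix - 1 / 18)), 0.03)
  expect_error(compute_modulogram(x, pac_config(amp_freqs = c(40, 600))),
               "Nyquist")
})

test_that("monophasicity is the median off-diagonal row correlation", {
  mk <- function(mat) structure(list(matrix = mat, freqs = seq_len(nrow(mat)),
                                     bin_centers = seq_len(ncol(mat))),
                                class = "ca3_modulogram")
  ## identical non-constant rows -> exactly 1
  r <- c(1, 3, 2, 5, 4, 6, 2, 1, 3, 2, 5, 4, 6, 2, 1, 3, 2, 5)
  expect_equal(monophasicity(mk(rbind(r, r, r) / sum(r))), 1)
  ## a row and its exact anticorrelated partner -> -1
  a <- seq_len(18); b <- rev(a)
  expect_equal(monophasicity(mk(rbind(a / sum(a), b / sum(b)))), -1)
  ## three rows with prescribed pairwise correlations {0.9, 0.1, -0.2}
  ## (a feasible correlation matrix) -> the median pair value, 0.1
  set.seed(21)
  base <- matrix(rnorm(3 * 18), 3)
  ## construct rows with exact sample correlations via Gram-Schmidt
  u1 <- scale(base[1, ])[, 1]
  u2 <- scale(residuals(lm(base[2, ] ~ u1)))[, 1]
  r12 <- 0.9; r13 <- 0.1; r23 <- -0.2
  x1 <- u1
  x2 <- r12 * u1 + sqrt(1 - r12^2) * u2
  a3 <- r13; b3 <- (r23 - r12 * r13) / sqrt(1 - r12^2)
  u3 <- scale(residuals(lm(base[3, ] ~ u1 + u2)))[, 1]
  x3 <- a3 * u1 + b3 * u2 + sqrt(1 - a3^2 - b3^2) * u3
  mat <- rbind(x1, x2, x3) + 10      # shift positive; correlation unchanged
  mat <- mat / rowSums(mat)
  expect_equal(monophasicity(mk(mat)), 0.1, tolerance = 1e-10)
  ## zero-variance row contributes 0 with a warning
  flatm <- mk(rbind(a / sum(a), rep(1 / 18, 18)))
  expect_warning(v <- monophasicity(flatm), "zero-variance")
  expect_equal(v, 0)
  expect_error(monophasicity(mk(matrix(1 / 18, 1, 18))), "at least 2")
})

test_that("recording-level monophasicity separates locked from scattered", {
  cfg <- pac_config(amp_freqs = seq(35, 95, by = 15))
  locked <- gen_pac_signal(pac_gen_config(duration = 30, seed = 5))
  m_locked <- monophasicity_of_recording(locked$ts, cfg)
  expect_length(m_locked$per_trial, 3)
  expect_gte(m_locked$overall, 0.95)
  nf <- 8
  scat <- gen_pac_signal(pac_gen_config(
    duration = 30, seed = 6,
    preferred_phase = seq(-pi, pi, length.out = nf + 1)[1:nf]))
  m_scat <- monophasicity_of_recording(scat$ts, pac_config())
  expect_lte(abs(m_scat$overall), 0.2)
  ## overall = median of per-trial values (odd count: the middle one)
  expect_equal(m_locked$overall, sort(m_locked$per_trial)[2])
  expect_error(monophasicity_of_recording(
    timeseries(rnorm(5000), 1000), cfg), "shorter")
})

test_that("monophasicity is invariant to scaling, offset and gain", {
  cfg <- pac_config(amp_freqs = seq(35, 95, by = 15))
  g <- gen_pac_signal(pac_gen_config(duration = 10, seed = 8))
  m1 <- monophasicity(compute_modulogram(g$ts, cfg))
  ## pure gain: exact (every stage is linear or gain-normalized)
  m_gain <- monophasicity(compute_modulogram(
    timeseries(7.3 * g$ts$samples, g$ts$fs), cfg))
  expect_lt(abs(m1 - m_gain), 1e-3)
  ## gain + DC offset: near-exact (offset perturbs only the reflect-pad
  ## edges)
  m_dc <- monophasicity(compute_modulogram(
    timeseries(7.3 * g$ts$samples + 11, g$ts$fs), cfg))
  expect_lt(abs(m1 - m_dc), 0.01)
})

test_that("phase-scrambled surrogates have near-zero median monophasicity", {
  ## random circular shift of the envelope per frequency destroys the
  ## phase-amplitude relation; median over seeds should sit near 0
  cfg <- pac_config(amp_freqs = seq(35, 95, by = 20))
  g <- gen_pac_signal(pac_gen_config(duration = 10, seed = 3))
  theta <- bandpass(g$ts, 3, 10)
  phase <- analytic_amplitude_phase(theta)$phase$samples
  brks <- seq(-pi, pi, length.out = 19)
  bin <- pmin(18L, pmax(1L, findInterval(phase, brks,
                                         rightmost.closed = TRUE)))
  envs <- lapply(cfg$amp_freqs, function(f)
    analytic_amplitude_phase(bandpass(g$ts, f - 10, f + 10))$amplitude$samples)
  vals <- vapply(1:50, function(s) {
    set.seed(s)
    mat <- t(vapply(envs, function(e) {
      e <- e[(seq_along(e) + sample.int(length(e), 1)) %% length(e) + 1L]
      mu <- vapply(1:18, function(b) mean(e[bin == b]), numeric(1))
      mu / sum(mu)
    }, numeric(18)))
    monophasicity(structure(list(matrix = mat, freqs = cfg$amp_freqs,
                                 bin_centers = brks[-19]),
                            class = "ca3_modulogram"))
  }, numeric(1))
  expect_lt(abs(median(vals)), 0.15)
})

test_that("KL modulation index has the stated closed-form values", {
  mk <- function(p) structure(list(matrix = matrix(p, 1), freqs = 1,
                                   bin_centers = seq_along(p)),
                              class = "ca3_modulogram")
  expect_equal(unname(coupling_strength(mk(rep(1 / 18, 18)))), 0)
  expect_equal(unname(coupling_strength(mk(c(1, rep(0, 17))))), 1)
  expect_equal(unname(coupling_strength(mk(c(0.5, 0.5, rep(0, 16))))),
               (log(18) - log(2)) / log(18), tolerance = 1e-12)
})

test_that("exact signed-rank p matches brute-force enumeration", {
  ## n = 8, all differences negative: p = 1/256
  a <- c(5, 6, 7, 8, 9, 10, 11, 12)
  b <- a + c(1, 2.5, 0.7, 3, 1.4, 2.2, 0.9, 4)
  expect_identical(paired_exact_signed_rank(a, b, "less"), 1 / 256)
  ## n = 1 single negative difference
  expect_equal(paired_exact_signed_rank(1, 2, "less"), 0.5)
  ## random samples against brute force over all 256 sign patterns and
  ## against the independent exact implementation in stats
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(8); y <- rnorm(8)
    for (alt in c("less", "greater")) {
      p <- paired_exact_signed_rank(x, y, alt)
      expect_equal(p, brute_signed_rank_p(x, y, alt))
      expect_equal(p, wilcox.test(x, y, paired = TRUE, alternative = alt,
                                  exact = TRUE)$p.value)
    }
  }
  expect_error(paired_exact_signed_rank(c(1, 2), c(1, 3), "less"), "zero")
  expect_error(paired_exact_signed_rank(c(1, 2), c(2, 3), "less"), "tied")
  expect_equal(paired_exact_signed_rank(c(1, 2), c(2, 3), "less",
                                        ties = "midrank"), 0.25)
})
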