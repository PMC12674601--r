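test_that("timeseries constructor enforces its invariants", {
  expect_error(timeseries(numeric(0), 10), "at least one")
  expect_error(timeseries(c(1, NA), 10), "finite")
  expect_error(timeseries(1:3, 0), "fs")
  ts <- timeseries(c(0, 1, -1), 10, units = "uV")
  expect_equal(ts_duration(ts), 0.3)
  expect_equal(ts_time(ts), c(0, 0.1, 0.2))
})

test_that("text I/O reads headers and reports bad rows by line", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# fs=10", "# units=uV", "0.0", "1.0", "-1.0"), f)
  ts <- read_timeseries(f, "text")
  expect_equal(ts$samples, c(0, 1, -1))
  expect_equal(ts$fs, 10)
  expect_equal(ts$units, "uV")

  writeLines(c("# fs=0", "1.0"), f)
  expect_error(read_timeseries(f, "text"), "invalid fs")
  writeLines(c("# units=uV", "1.0"), f)
  expect_error(read_timeseries(f, "text"), "fs")
  writeLines(c("# fs=10", "1.0", "oops", "2.0"), f)
  expect_error(read_timeseries(f, "text"), "line 3")
})

test_that("binary container round-trips bit-exactly, text to precision", {
  set.seed(42)
  ts <- timeseries(rnorm(257), fs = 4096, units = "uV", t0 = 1.25)
  fb <- tempfile(); ft <- tempfile()
  write_timeseries(ts, fb, "binary")
  back <- read_timeseries(fb, "binary")
  expect_identical(back$samples, ts$samples)
  expect_identical(back$fs, ts$fs)
  expect_identical(back$t0, ts$t0)
  write_timeseries(ts, ft, "text", digits = 15)
  back_t <- read_timeseries(ft, "text")
  expect_equal(back_t$samples, ts$samples, tolerance = 1e-12)
  expect_error(read_timeseries(ft, "binary"), "container")
})

test_that("raster container validates entries and round-trips", {
  expect_error(raster(matrix(2, 1, 3), 31), "0 or 1")
  expect_error(raster(matrix(0, 1, 3), 0), "fs_frames")
  r <- raster(matrix(rbinom(60, 1, 0.3), 4, 15), 31)
  f <- tempfile()
  write_raster(r, f)
  back <- read_raster(f)
  expect_equal(back$spikes, r$spikes)
  expect_equal(back$fs_frames, 31)
})

test_that("trial segmentation follows the floor rule and conserves samples", {
  ts <- timeseries(seq_len(35 * 100), fs = 100)
  tr <- segment_trials(ts, 10)
  expect_length(tr$trials, 3)
  expect_length(segment_trials(timeseries(seq_len(1000), 100), 10)$trials, 1)
  expect_length(segment_trials(timeseries(seq_len(999), 100), 10)$trials, 0)
  expect_error(segment_trials(ts, 0), "trial_len")
  ## conservation: sum of trial lengths + remainder = record length
  n_in_trials <- sum(vapply(tr$trials, function(x) length(x$samples), 1))
  expect_equal(n_in_trials + (length(ts$samples) - n_in_trials),
               length(ts$samples))
  expect_true(length(ts$samples) - n_in_trials < 10 * 100)
  ## trials are consecutive and non-overlapping
  expect_equal(tr$trials[[2]]$samples[1], ts$samples[1001])
})

test_that("bandpass preserves in-band content and rejects out-of-band", {
  s6 <- sine_ts(6)
  filt <- bandpass(s6, 3, 10)
  expect_lt(abs(sd(filt$samples) / sd(s6$samples) - 1), 0.05)
  expect_equal(length(filt$samples), length(s6$samples))
  s50 <- sine_ts(50)
  resid <- bandpass(s50, 3, 10)
  expect_lt(sqrt(mean(resid$samples^2)) / sqrt(mean(s50$samples^2)), 0.1)
  expect_error(bandpass(s6, 400, 600), "Nyquist")
  expect_error(bandpass(s6, 10, 3), "Nyquist")
})

test_that("bandpass is idempotent and band powers match the periodogram", {
  set.seed(7)
  wn <- timeseries(rnorm(30000), 1000)
  once <- bandpass(wn, 30, 80)
  twice <- bandpass(once, 30, 80)
  expect_lt(sqrt(mean((once$samples - twice$samples)^2)) /
              sqrt(mean(once$samples^2)), 0.2)
  ## derived oracle: band variance after filtering equals direct spectral
  ## integration of the unfiltered signal over the band
  spec <- periodogram(wn, seg_len = 2)
  for (band in list(c(30, 80), c(80, 160))) {
    filt <- bandpass(wn, band[1], band[2])
    expect_lt(abs(var(filt$samples) /
                    band_power(spec, band[1], band[2]) - 1), 0.1)
  }
})

test_that("analytic amplitude and phase recover closed forms", {
  s <- sine_ts(6, amp = 2)
  ap <- analytic_amplitude_phase(s)
  interior <- 500:9500
  expect_lt(max(abs(ap$amplitude$samples[interior] - 2)), 0.04)
  ## phase 0 at the cosine peak
  pk <- which.max(s$samples[1000:2000]) + 999
  expect_lt(abs(ap$phase$samples[pk]), 0.05)
  ## sign flip: amplitude invariant, phase shifted by pi
  ap2 <- analytic_amplitude_phase(timeseries(-s$samples, s$fs))
  expect_equal(ap2$amplitude$samples[interior],
               ap$amplitude$samples[interior], tolerance = 1e-6)
  dphi <- (ap2$phase$samples - ap$phase$samples)[interior] %% (2 * pi)
  expect_lt(max(abs(dphi - pi)), 1e-3)
  expect_error(analytic_amplitude_phase(timeseries(1:10, 10)), "16")
})

test_that("instantaneous frequency tracks a chirp", {
  fs <- 1000; t <- (0:(10 * fs - 1)) / fs
  f_inst <- 5 + 0.3 * t                       # 5 -> 8 Hz over 10 s
  x <- timeseries(cos(2 * pi * (5 * t + 0.15 * t^2)), fs)
  ph <- analytic_amplitude_phase(x)$phase$samples
  f_est <- diff(signal::unwrap(ph)) * fs / (2 * pi)
  interior <- 500:9000
  expect_lt(max(abs(f_est[interior] - f_inst[interior])), 0.2)
})

test_that("periodogram satisfies Parseval and locates line spectra", {
  set.seed(3)
  wn <- timeseries(rnorm(60000), 1000)
  sp <- periodogram(wn, seg_len = 2)
  expect_true(all(diff(sp$freqs) > 0))
  expect_true(all(sp$power >= 0))
  df <- diff(sp$freqs)[1]
  expect_lt(abs(sum(sp$power) * df / var(wn$samples) - 1), 0.05)
  s <- sine_ts(6, dur = 30)
  sp6 <- periodogram(s, seg_len = 4)
  expect_lt(abs(sp6$freqs[which.max(sp6$power)] - 6), diff(sp6$freqs)[1])
  ## two-line spectrum: power ratio = amplitude ratio squared
  t <- (0:(30 * 1000 - 1)) / 1000
  mix <- timeseries(2 * sin(2 * pi * 6 * t) + 1 * sin(2 * pi * 40 * t), 1000)
  spm <- periodogram(mix, seg_len = 4)
  p6 <- band_power(spm, 4, 8); p40 <- band_power(spm, 38, 42)
  expect_lt(abs(p6 / p40 - 4), 0.4)
  expect_error(periodogram(s, seg_len = 60), "longer")
  expect_error(periodogram(timeseries(1:100, 1000), seg_len = 0.05), "64")
})

test_that("Morlet spectrogram localizes power in time and frequency", {
  z <- timeseries(numeric(2000), 1000)
  expect_true(all(morlet_spectrogram(z, c(10, 40))$power == 0))
  expect_error(morlet_spectrogram(z, numeric(0)), "non-empty")
  expect_error(morlet_spectrogram(z, 600), "fs/2")
  s40 <- sine_ts(40, dur = 2)
  tf <- morlet_spectrogram(s40, c(10, 25, 40, 60, 90))
  interior <- 300:1700
  dominant <- apply(tf$power[, interior], 2, which.max)
  expect_true(all(dominant == 3))
  ## 200 ms 90 Hz burst in light noise: onset recovered within 50 ms
  set.seed(11)
  fs <- 1000; n <- 4000
  x <- rnorm(n, 0, 0.1)
  on_true <- 2.0
  idx <- (on_true * fs + 1):(on_true * fs + 200)
  x[idx] <- x[idx] + sin(2 * pi * 90 * (seq_along(idx)) / fs)
  tfb <- morlet_spectrogram(timeseries(x, fs), 90)
  row <- tfb$power[1, ]
  onset_est <- tfb$times[which(row > 0.5 * max(row))[1]]
  expect_lt(abs(onset_est - on_true), 0.05)
  ## energy concentration of the 90 Hz row inside the burst
  sd_w <- 7 / (2 * pi * 90)
  inburst <- tfb$times >= on_true - sd_w & tfb$times <= on_true + 0.2 + sd_w
  expect_gt(sum(row[inburst]) / sum(row), 0.8)
})
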