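test_that("gating kinetics match the model definition at key voltages", {
  ## persistent-Na: tau 1 ms (interneurons), 15 ms (pyramidal),
  ## half-activation -52.3 mV
  for (V in c(-80, -52.3, -20)) {
    expect_equal(unname(gating_kinetics(V, "OLM", "mp")["tau"]), 1)
    expect_equal(unname(gating_kinetics(V, "basket", "mp")["tau"]), 1)
    expect_equal(unname(gating_kinetics(V, "pyramidal", "mp")["tau"]), 15)
  }
  expect_equal(unname(gating_kinetics(-52.3, "OLM", "mp")["inf"]), 0.5)
  ## O-LM kinetics agree with an independent scalar transcription
  for (V in c(-90, -70.1, -50, -38 + 1e-4, -10, 20))
    for (g in c("m", "h", "n", "mp", "a", "b", "r"))
      expect_equal(unname(gating_kinetics(V, "OLM", g)),
                   unname(olm_gate_kin_transcription(V, g)),
                   tolerance = 1e-10, label = paste("OLM", g, "at", V))
  ## a, b, r are O-LM-only gates
  expect_error(gating_kinetics(-60, "basket", "a"), "not valid")
  expect_error(gating_kinetics(-60, "pyramidal", "r"), "not valid")
  expect_error(gating_kinetics(NaN, "OLM", "m"), "finite")
})

test_that("removable singularities are continuous analytic limits", {
  ## O-LM alpha_m is singular at V = -38; the limit must be finite and
  ## continuous to 1e-6 against V = -38 +- 1e-4
  k0 <- gating_kinetics(-38, "OLM", "m")
  expect_true(all(is.finite(k0)))
  ## L'Hopital: alpha_m -> 1 as V -> -38, so inf and tau have closed forms
  bm <- 4 * exp(-27 / 18)
  expect_equal(unname(k0["tau"]), 1 / (1 + bm), tolerance = 1e-12)
  expect_equal(unname(k0["inf"]), 1 / (1 + bm), tolerance = 1e-12)
  kp <- gating_kinetics(-38 + 1e-4, "OLM", "m")
  km <- gating_kinetics(-38 - 1e-4, "OLM", "m")
  expect_lt(max(abs(k0 - kp)), 1e-5)
  expect_lt(max(abs(k0 - km)), 1e-5)
  ## same for the other rational gates
  for (case in list(c("OLM", "n", 25), c("basket", "m", -35),
                    c("basket", "n", -34), c("pyramidal", "m", -54),
                    c("pyramidal", "n", -52))) {
    Vs <- as.numeric(case[3])
    k0 <- gating_kinetics(Vs, case[1], case[2])
    kp <- gating_kinetics(Vs + 1e-4, case[1], case[2])
    expect_true(all(is.finite(k0)))
    expect_lt(max(abs(k0 - kp)), 1e-5)
  }
  ## steady states bounded in [0, 1], taus positive, over a wide range
  for (V in seq(-120, 60, by = 7.3)) {
    for (ct in c("OLM", "basket", "pyramidal")) {
      gates <- if (ct == "OLM") c("m", "h", "n", "mp", "a", "b", "r")
               else c("m", "h", "n", "mp")
      for (g in gates) {
        k <- gating_kinetics(V, ct, g)
        expect_true(k["inf"] >= 0 && k["inf"] <= 1 && k["tau"] > 0)
      }
    }
  }
})

test_that("cell_rhs reproduces the current-balance arithmetic", {
  ## leak only: dV/dt = -gL (V - EL) / C = -0.05*10/1.3
  p <- cell_params("OLM", gNa = 0, gNaP = 0, gK = 0, gh = 0, gA = 0)
  r <- cell_rhs(-60, rep(0, 7), p)
  expect_equal(r$dV, -0.05 * (-60 + 70) / 1.3, tolerance = 1e-12)
  ## equilibrium: V = EL, active conductances off, gates at steady state
  p2 <- cell_params("basket", gNa = 0, gNaP = 0, gK = 0)
  ss <- vapply(c("m", "h", "n", "mp"), function(g)
    gating_kinetics(-65, "basket", g)["inf"], numeric(1))
  r2 <- cell_rhs(-65, ss, p2)
  expect_equal(r2$dV, 0, tolerance = 1e-12)
  expect_equal(max(abs(r2$dgates)), 0, tolerance = 1e-10)
  ## full O-LM parameter set against the double-entry transcription
  p3 <- cell_params("OLM")
  gates <- c(m = 0.1, h = 0.6, n = 0.3, mp = 0.2, a = 0.4, b = 0.5,
             r = 0.15)
  for (V in c(-70, -55, -30, 10)) {
    r3 <- cell_rhs(V, gates, p3, I_app = 0.7, I_syn = 0.2)
    expect_equal(r3$dV, olm_rhs_transcription(V, gates, p3, 0.7, 0.2),
                 tolerance = 1e-10)
  }
  ## zero persistent-Na conductance removes the NaP term exactly
  pa <- cell_params("pyramidal", gNaP = 0)
  pb <- cell_params("pyramidal", gNaP = 0.3)
  ga <- c(m = 0.1, h = 0.6, n = 0.3, mp = 1)
  dv_a <- cell_rhs(-50, ga, pa)$dV
  dv_b <- cell_rhs(-50, ga, pb)$dV
  expect_equal(dv_b - dv_a, -0.3 * 1 * (-50 - 50) / 1, tolerance = 1e-10)
})

test_that("compartment coupling follows the cable formula", {
  geo <- pyramidal_geometry()
  g <- compartment_coupling(geo)
  ## hand calculation for the soma-apical1 pair (cm units)
  Ra <- 150
  half_R <- function(l_um, d_um)
    2 * Ra * (l_um * 1e-4) / (pi * (d_um * 1e-4)^2)
  G <- 1 / (half_R(20, 20) + half_R(150, 2))
  a_soma <- pi * (20e-4) * (20e-4)
  a_ap <- pi * (2e-4) * (150e-4)
  expect_equal(g["soma", "apical1"], 1000 * G / a_soma, tolerance = 1e-12)
  expect_equal(g["apical1", "soma"], 1000 * G / a_ap, tolerance = 1e-12)
  ## charge conservation: g[k,j] * area_k symmetric
  areas <- pi * (geo$diameters * 1e-4) * (geo$lengths * 1e-4)
  flow <- g * areas  # row compartment area
  expect_equal(flow, t(flow), tolerance = 1e-12)
  ## two identical cylinders couple symmetrically
  geo_eq <- pyramidal_geometry(lengths = rep(100, 5), diameters = rep(2, 5))
  g_eq <- compartment_coupling(geo_eq)
  expect_equal(g_eq["soma", "apical1"], g_eq["apical1", "soma"])
  ## doubling Ra halves every coupling
  g2 <- compartment_coupling(pyramidal_geometry(Ra = 300))
  expect_equal(g2, g / 2, tolerance = 1e-12)
  expect_error(pyramidal_geometry(lengths = c(0, 20, 150, 150, 150)),
               "dimensions")
})

test_that("leak-only cell relaxes to E_L with the analytic exponential", {
  cfg <- circuit_config(counts = c(0, 1, 0),
                        basket = cell_params("basket", gNa = 0, gNaP = 0,
                                             gK = 0),
                        drive = drive_spec(I_app_mean = c(OLM = 0, basket = 0,
                                                          pyramidal = 0),
                                           I_app_noise_sd = c(OLM = 0,
                                                              basket = 0,
                                                              pyramidal = 0)),
                        dt = 0.002, duration = 0.05, rec_fs = 5e5,
                        v_init = -55)
  res <- simulate_circuit(cfg, seed = 1)
  tt <- seq_len(nrow(res$V)) / cfg$rec_fs * 1000   # ms
  exact <- -65 + 10 * exp(-tt / 10)                # tau = C/gL = 10 ms
  expect_lt(max(abs(res$V[, 1] - exact)), 1e-3)
  expect_lt(abs(res$V[round(0.01 * cfg$rec_fs), 1] -
                  (-65 + 10 * exp(-1))), 1e-3)
})

test_that("a driven basket cell spikes periodically, rate monotone in drive", {
  rates <- vapply(c(0.5, 1, 2, 3), function(I) {
    cfg <- circuit_config(counts = c(0, 1, 0),
      drive = drive_spec(I_app_mean = c(OLM = 0, basket = I, pyramidal = 0),
                         I_app_noise_sd = c(OLM = 0, basket = 0,
                                            pyramidal = 0)),
      dt = 0.01, duration = 2)
    length(simulate_circuit(cfg, seed = 1)$spike_times[[1]]) / 2
  }, numeric(1))
  expect_true(all(rates > 5))
  expect_true(all(diff(rates) > 0))
  ## inter-spike intervals nearly constant (periodic, noiseless)
  cfg <- circuit_config(counts = c(0, 1, 0),
    drive = drive_spec(I_app_mean = c(OLM = 0, basket = 1.5, pyramidal = 0),
                       I_app_noise_sd = c(OLM = 0, basket = 0,
                                          pyramidal = 0)),
    dt = 0.01, duration = 2)
  st <- simulate_circuit(cfg, seed = 1)$spike_times[[1]]
  isi <- diff(st[-1])
  expect_lt(diff(range(isi)) / mean(isi), 0.05)
})

test_that("halving dt barely changes a noiseless single-cell run", {
  run_at <- function(dt, I, gNaP = 0.07) {
    cfg <- circuit_config(counts = c(0, 1, 0),
      basket = cell_params("basket", gNaP = gNaP),
      drive = drive_spec(I_app_mean = c(OLM = 0, basket = I, pyramidal = 0),
                         I_app_noise_sd = c(OLM = 0, basket = 0,
                                            pyramidal = 0)),
      dt = dt, duration = 2, rec_fs = 1000)
    simulate_circuit(cfg, seed = 1)
  }
  ## spiking run: spike count changes by at most one
  a <- run_at(0.01, 1.2); b <- run_at(0.005, 1.2)
  expect_lte(abs(length(a$spike_times[[1]]) - length(b$spike_times[[1]])), 1)
  ## subthreshold run: the voltage trajectory itself converges
  ## (spiking trajectories accumulate phase shifts, so pointwise RMS is
  ## only meaningful below threshold)
  a0 <- run_at(0.01, 0.1, gNaP = 0); b0 <- run_at(0.005, 0.1, gNaP = 0)
  expect_length(a0$spike_times[[1]], 0)
  expect_lt(sqrt(mean((a0$V[, 1] - b0$V[, 1])^2)), 0.5)
})

test_that("simulation is deterministic and raster matches threshold crossings", {
  cfg <- small_circuit(duration = 2)
  r1 <- simulate_circuit(cfg, seed = 5)
  r2 <- simulate_circuit(cfg, seed = 5)
  expect_identical(r1$V, r2$V)
  expect_identical(r1$raster$spikes, r2$raster$spikes)
  expect_identical(r1$lfp$samples, r2$lfp$samples)
  ## raster consistency at full recording resolution: every spike is an
  ## upward crossing of the threshold in the recorded soma trace
  cfg_hi <- circuit_config(counts = c(0, 1, 0),
    drive = drive_spec(I_app_mean = c(OLM = 0, basket = 1.5, pyramidal = 0),
                       I_app_noise_sd = c(OLM = 0, basket = 0.2,
                                          pyramidal = 0)),
    dt = 0.01, duration = 1, rec_fs = 1e5)
  res <- simulate_circuit(cfg_hi, seed = 3)
  v <- res$V[, 1]
  crossings <- which(v[-1] >= 0 & v[-length(v)] < 0) / cfg_hi$rec_fs
  st <- res$spike_times[[1]]
  expect_equal(length(st), length(crossings))
  expect_lt(max(abs(st - crossings)), 2e-4)
})

test_that("gates stay in [0, 1] through vigorous spiking", {
  ## debug_gates asserts boundedness inside the integrator at every step
  cfg <- small_circuit(duration = 1)
  expect_no_error(simulate_circuit(cfg, seed = 3, debug_gates = TRUE))
})

test_that("twin runs share noise and diverge only via the perturbation", {
  cfg <- small_circuit(duration = 2)
  tw0 <- perturbed_twin_simulation(cfg, delta_V0 = 0, seed = 4)
  expect_identical(tw0$run1$V, tw0$run2$V)
  tw <- perturbed_twin_simulation(cfg, delta_V0 = 1e-3, seed = 4)
  d <- abs(tw$run1$lfp$samples - tw$run2$lfp$samples)
  expect_gt(mean(tail(d, 500)), mean(head(d, 50)))
  expect_error(perturbed_twin_simulation(cfg, -1), ">= 0")
  ## contracting leak-only network: perturbation decays
  cfg_leak <- circuit_config(counts = c(0, 0, 2),
    pyr = cell_params("pyramidal", gNa = 0, gNaP = 0, gK = 0),
    drive = drive_spec(I_app_mean = c(OLM = 0, basket = 0, pyramidal = 0),
                       I_app_noise_sd = c(OLM = 0, basket = 0,
                                          pyramidal = 0.2)),
    dt = 0.01, duration = 1)
  twl <- perturbed_twin_simulation(cfg_leak, delta_V0 = 0.1, seed = 2)
  dl <- abs(twl$run1$V[, "pyr1.soma"] - twl$run2$V[, "pyr1.soma"])
  expect_lt(dl[length(dl)], dl[1] / 10)
})

test_that("LFP proxy is the mean-subtracted mean pyramidal soma", {
  cfg <- circuit_config(counts = c(0, 0, 1), dt = 0.05, duration = 1)
  res <- simulate_circuit(cfg, seed = 1)
  soma <- res$V[, "pyr1.soma"]
  expect_equal(res$lfp$samples, soma - mean(soma))
  ## no pyramidal cells -> no proxy
  cfg0 <- circuit_config(counts = c(1, 1, 0), dt = 0.05, duration = 0.5)
  res0 <- simulate_circuit(cfg0, seed = 1)
  expect_null(res0$lfp)
  expect_error(lfp_proxy(res0), "pyramidal")
})
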