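# ca3dyn

Hodgkin-Huxley simulation of a hippocampal CA3-like microcircuit with
persistent sodium currents, and the analytics used to characterise its
local field potential (LFP) and spiking output — written for
computational neuroscientists studying how a gain-of-function sodium
channel (the biophysical proxy for Nav1.6 / *SCN8A* epileptic
encephalopathy) disrupts hippocampal network rhythms, and for anyone who
needs tested reference implementations of these statistics.

The package covers:

* **Circuit simulation** — O-LM and basket interneurons (single
  compartment) and five-compartment pyramidal cells, each with transient
  Na (m³h), persistent Na (m_p), delayed-rectifier K (n⁴) and leak
  currents (plus h- and A-currents in O-LM cells), kinetic synapses,
  noisy drive, spike rasters and an LFP proxy. The persistent current
  I_NaP = g_NaP · m_p · (V − E_Na), with m_p half-activating at
  −52.3 mV (slope 6.8 mV, τ = 1 ms in interneurons, 15 ms in pyramidal
  cells), is the mutation's dial.
* **Theta-gamma monophasicity** — a modulogram of mean gamma-band
  (25–115 Hz) Hilbert amplitude per theta (3–10 Hz) phase bin (18 bins
  over [−π, π]), summarized as the median Pearson correlation between
  all pairs of frequency rows, per 10-s trial, with the recording-level
  value the median across trials. High values mean all gamma
  frequencies lock to one theta phase.
* **Instability analytics** — the noise-robust 0–1 test for chaos
  (drive p(n+1) = p(n) + φ(n)cos(cn), q likewise; K = median over 100
  random c of corr(n, M_c(n)) with additive noise σ = 0.5 in the mean
  square displacement), applied to theta-filtered LFPs and to spike
  rasters; and a stochastic largest Lyapunov exponent Λ fitted to the
  log divergence of twin simulations run under identical noise with
  perturbed initial voltages.
* **Event detection** — sustained high-amplitude runs (≥ 30 s at ≥ 5×
  the preceding 30 s RMS), spike / sharp-wave / long-duration-discharge
  classification, gamma (30–80 Hz) and high-gamma/ripple (80–160 Hz)
  burst detection, calcium-raster synchrony.
* **Genetic-algorithm fitting** — a control stage over drives,
  conductances and connectivity, and a mutant stage restricted to
  persistent-Na strengths and cell counts with theta power preserved.
* **Synthetic data** — seeded generators with exact ground truth for
  PAC signals, chaotic/periodic benchmarks, event-laden LFPs and
  synchrony-controlled rasters, so every stage is testable offline.

## Worked example

```r
library(ca3dyn)

## simulate the default theta-gamma-capable circuit (4 O-LM, 3 basket,
## 6 pyramidal cells) for 20 s
cfg <- circuit_config(dt = 0.05, duration = 20)
res <- simulate_circuit(cfg, seed = 11)
res
#> <simresult> 37 units, 20.000 s @ 1000 Hz, 3575 spikes

## theta-gamma coupling of the simulated LFP
monophasicity_of_recording(res$lfp)$overall
#> [1] 0.9697544

## theta instability (0-1 chaos test on the 3-10 Hz component)
theta_instability(res$lfp, chaos_config(downsample_to = 100))$K
#> [1] 0.02087205

## raising persistent Na 3x, losing O-LM cells, adding pyramidal cells
mut <- apply_params(cfg, c(nap_scale = 3, counts.OLM = 2,
                           counts.pyramidal = 9))
monophasicity_of_recording(simulate_circuit(mut, seed = 11)$lfp)$overall
#> [1] 0.3933523

## the same altered composition with the control persistent Na restored
hyb <- apply_params(cfg, c(counts.OLM = 2, counts.pyramidal = 9))
monophasicity_of_recording(simulate_circuit(hyb, seed = 11)$lfp)$overall
#> [1] 0.9007089
```

The control circuit shows strongly monophasic theta-gamma coupling
(≈ 0.97: every gamma band locks to the same theta phase) and a stable
theta rhythm (K ≈ 0). The persistent-Na/cell-count manipulation leaves
oscillations present but scatters the gamma-to-theta phase relation
(monophasicity ≈ 0.39) — the network-level signature the fitting stages
work with. Restoring the control persistent-Na conductance in the
mutant circuit recovers monophasicity only partially (≈ 0.90 versus
≈ 0.97), because the altered cell composition matters on its own.

The chaos test classifies benchmark series as designed:

```r
chaos_k_statistic(gen_chaos_benchmark("logistic", 1e4, list(r = 4, x0 = 0.2)))$K
#> [1] 0.9983406   # chaotic map: K near 1
chaos_k_statistic(gen_chaos_benchmark("sine", 1e4, list(f = 1, fs = 13.7)))$K
#> [1] -0.0002811734  # periodic signal: K near 0
```

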