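---
title: "Models and methods in ca3dyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ca3dyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ca3dyn simulates a small hippocampal CA3-like microcircuit and implements
the analytics used to characterise its output and comparable experimental
recordings: theta-gamma phase-amplitude coupling and a monophasicity
statistic, a noise-robust 0-1 test for chaos, stochastic largest Lyapunov
exponents from perturbed twin simulations, epileptiform event detection,
calcium-raster synchrony, and a two-stage genetic-algorithm fit of circuit
parameters to electrophysiological feature targets. This vignette explains
the models, the tunable parameters, and the numerical and design choices
behind them.

## The circuit model

Three conductance-based cell types interact:

* **O-LM cells** — slow-spiking, somatostatin-type interneurons.
  Single-compartment Hodgkin-Huxley model with transient Na (gates
  $m^3h$), persistent Na ($m_p$), delayed-rectifier K ($n^4$), leak,
  an h-current (gate $r$) and an A-current (gates $a\,b$). Capacitance
  1.3 uF/cm^2; leak 0.05 mS/cm^2 at -70 mV.
* **Basket cells** — fast-spiking interneurons in the Wang-Buzsaki
  lineage, single compartment with Na, persistent Na, K and leak
  (capacitance 1 uF/cm^2; leak 0.1 mS/cm^2 at -65 mV).
* **Pyramidal cells** — five coupled cylindrical compartments (basal
  dendrite 200 x 2 um, soma 20 x 20 um, three apical dendrites 150 x 2
  um; axial resistivity 150 Ohm cm), each compartment carrying Na,
  persistent Na, K and leak in the Traub/Migliore lineage.

The persistent sodium current $I_{NaP} = g_{NaP}\, m_p (V - E_{Na})$ is
the biophysical proxy for gain-of-function Nav1.6: $m_p$ has
half-activation -52.3 mV, slope 6.8 mV, and a fixed time constant (1 ms
in interneurons, 15 ms in pyramidal cells). Setting $g_{NaP} = 0$ in all
cell types removes the term exactly and recovers the base model.

Every current-balance equation has the form
$C\,dV/dt = I_{app} - \sum I_{ion} - I_{syn} (+ I_{conn})$, with the
gate kinetics in the standard form $x_\infty = \alpha/(\alpha+\beta)$,
$\tau_x = 1/(\alpha+\beta)$. Removable singularities of the rational
rate functions (for example the O-LM $\alpha_m$ at $V = -38$ mV) are
evaluated by their analytic limits; tests assert continuity to $10^{-6}$
across the singular points. Reversal potentials and the non-leak maximal
conductances are not part of the model definition we inherit, so the
package ships lineage-conventional defaults (`cell_params()`) that are
explicitly starting points for fitting.

The h-current activation uses
$r_\infty = 1/(1+\exp((V - v_{50})/10.2))$; $v_{50}$ appears as a free
parameter of the model and defaults to -80 mV, exposed in
`cell_params("OLM")`.

**Synapses.** The model lineage leaves the synapse model implicit, so we
use the standard first-order kinetic synapse: each presynaptic cell
drives a gate $s$ with
$ds/dt = F(V_{pre})(1-s)/\tau_{rise} - s/\tau_{decay}$,
$F(V) = 1/(1+e^{-V/2})$, and
$I_{syn} = w \sum_i s_i (V_{post} - E_{rev})$. Defaults: GABA-A at
-80 mV (decay 9 ms from basket cells, 20 ms from O-LM cells, which
target the distal apical compartment), AMPA at 0 mV (decay 2 ms). The
weight $w$ is the conductance contributed *per presynaptic cell*, so a
projection's total drive scales with its population size. This was a
genuinely open design choice (the alternative normalizes $w$ by
$N_{pre}$, holding total drive fixed); we chose per-cell weights because
the fitting stages optimize cell counts, and counts are only meaningful
fitting targets if changing them changes the dynamics — under
$N_{pre}$-normalization an O-LM population of 2 and of 8 produce nearly
indistinguishable network statistics, which we verified empirically
before settling the choice. All nine population pairs are
connectable; the shipped default weights place the circuit in a regime
with monophasic theta-gamma coupling (O-LM inhibition paces a 3-10 Hz
rhythm on the pyramidal population while the basket-pyramidal loop
generates gamma riding on it).

**Compartment coupling.** The model geometry fixes lengths, diameters
and $R_a$ but not the coupling formula; we use the standard cable
conductance between cylinder midpoints,
$G = 1/(R_j/2 + R_k/2)$ with $R_i = 4 R_a l_i / (\pi d_i^2)$, expressed
per membrane area of the receiving compartment. Total axial charge flow
is conserved by construction (`compartment_coupling()` is tested against
a hand calculation and for symmetry).

**Integration.** Fixed step, default $dt = 0.01$ ms: exponential Euler
for gating and synaptic gates (exact for the linear gate ODE at frozen
voltage) and forward Euler for voltages. Gate steady states and decay
factors are tabulated on a 0.02 mV grid with linear interpolation (the
exact kinetics remain available through `gating_kinetics()` and
`cell_rhs()`, which the table is tested against). Gates are clamped to
[0, 1] after every step and optionally asserted (`debug_gates`).
Accuracy is guarded by a convergence property — halving $dt$ changes the
spike count of a noiseless 2 s run by at most one spike — rather than by
trusting any particular step size. Network simulations in this vignette
and in the fitting stages use $dt = 0.05$ ms, which passes the same
convergence check for the regimes involved.

**Drive noise.** The applied-current noise process is not specified by
the model lineage; we use white Gaussian noise, adding
$\sigma\,\eta/\sqrt{dt}$ each step so the spectral intensity is
independent of the step size. This is flagged in `drive_spec()`.

**Spikes and LFP.** A spike is an upward crossing of 0 mV (HH spikes
overshoot it robustly) with a 2 ms de-bounce; pyramidal spikes are taken
at the soma. The simulated LFP observable is not defined by the source
model, so the package uses the simplest proxy whose theta/gamma content
matches the analyses: the mean pyramidal somatic potential,
mean-subtracted, recorded at 1 kHz. Users can substitute a
synaptic-current proxy by operating on the returned voltage matrix.

## Theta-gamma monophasicity

For each amplitude frequency from 25 to 115 Hz the LFP is band-pass
filtered and its Hilbert envelope extracted; theta phase comes from the
analytic signal of the 3-10 Hz filtered trace. The envelope means over
18 phase bins spanning $[-\pi, \pi]$, normalized to sum to one, form one
modulogram row per frequency. Monophasicity is the median Pearson
correlation over all distinct row pairs: near 1 when every gamma
frequency couples to the same theta phase, near 0 when preferred phases
scatter. Recordings are processed in non-overlapping 10 s trials and
summarized by the median across trials (mean-of-central-pair for even
counts).

Choices the definition leaves open, and our defaults: amplitude
frequency step 5 Hz (a standard comodulogram granularity); +-10 Hz
bandwidth per center, which must exceed the theta rate to capture the
modulation sidebands; Pearson correlation ("correlated" unqualified;
Spearman available via `cor_method`); zero-variance rows contribute 0
with a warning rather than propagating NaN. Assembloid-rate (4096 Hz)
and clinical-rate (5000 Hz) inputs are processed identically without
resampling. The per-frequency coupling strength exported as
`coupling_strength()` is the Tort-style KL modulation index; the
statistic behind the original coupling-strength comparison is not
specified, so this index is a documented stand-in.

Filtering is zero-phase (forward-backward Butterworth, order 4 per pass,
order reduced automatically if a narrow band makes the design unstable)
— mandatory for phase-coupling work, where group delay would bias the
phase estimate. Because the double pass squares the magnitude response,
the design corners are widened slightly (factor 0.95, calibrated so
white-noise band variance matches direct spectral integration over the
nominal band). Signals are reflect-padded by about four filter time
constants and trimmed after filtering to suppress transients in short
trials.

## The 0-1 test for chaos

`chaos_k_statistic()` drives the two-dimensional system
$p(n+1) = p(n) + \phi(n)\cos(cn)$, $q(n+1) = q(n) + \phi(n)\sin(cn)$
with the observed series $\phi$ and computes the time-averaged mean
square displacement $M_c(n)$, plus an additive noise term
$\sigma\,\eta_n$ with $\eta$ uniform on $[-1/2, 1/2]$ and
$\sigma = 0.5$ (the noise-robust variant of the test; the uniform
distribution is its standard choice). $K_c$ is the correlation of
$M_c(n)$ with the lag $n$, and the statistic $K$ is the median over 100
draws of $c$ uniform on $(0, 2\pi)$ — the median mitigates resonant $c$
values that the restricted-range variant would exclude; the range is
configurable. Lags run to 10% of the series length (standard bias
control for MSD estimates), and the displacement sums are evaluated over
the $N-n$ valid pairs via FFT autocorrelation. $K \to 1$ indicates
chaos, $K \approx 0$ periodicity.

Applied to LFP theta (`theta_instability()`), the signal is band-passed
3-10 Hz, downsampled to 50 Hz by default (LFPs at several kHz are far
oversampled for the test, which assumes coarse sampling relative to the
dynamics; the rate is configurable and reported), and normalized to unit
RMS so the statistic is amplitude-invariant. Applied to rasters
(`raster_instability()`), the raster is collapsed to the per-frame
population spike count — the minimal-assumption scalar reduction, which
for a single cell reduces exactly to the test on that cell's 0/1 train.

## Stochastic largest Lyapunov exponent

`perturbed_twin_simulation()` runs the circuit twice under the identical
noise sequence (same seed and draw order) with all initial voltages of
the second run offset by $\delta V_0$, so any divergence reflects the
dynamics, not the stochastic drive. `lyapunov_from_twin_runs()` measures
the divergence on the amplitude scale,
$\epsilon(t) = |Q^{(1)}(t) - Q^{(2)}(t)| / \sqrt{\epsilon_{max}}$ with
$\epsilon_{max} = (\max Q^{(1)} - \min Q^{(2)})^2$, and fits
$\Lambda$ as the least-squares slope of $\ln\epsilon$ over a window
running by default from the end of the transient (first sample above
$10\,\epsilon(0)$) to saturation (first sample above 0.5), excluding
exact zeros. The amplitude scale is a deliberate choice: it makes
$\epsilon(t) = \epsilon(0)e^{\Lambda t}$ recover the conventional
exponent for constructed exponential divergence or contraction and the
known $\ln 2$ for twin logistic-map runs, whereas a cumulative sum of
squared differences doubles growth rates and saturates to a constant for
contracting pairs (its slope can never estimate a negative exponent).
The running-RMS cumulative variant remains available via
`cumulative = TRUE`. Identical runs return a no-divergence sentinel
rather than an exponent.

## Event detection

* **Sustained runs**: a run of at least 30 s whose RMS is at least 5x
  the RMS of the immediately preceding 30 s. Per-second RMS, 1 s hop;
  the baseline is frozen at run onset so the event cannot inflate its
  own reference; overlapping detections merge. The duration and ratio
  are exact rule boundaries (29 s or 4.9x do not count) and are tested
  as such.
* **Discharges**: samples exceeding 6 robust SDs (1.4826 x MAD, immune
  to contamination by the events themselves; 6 clears the Gaussian
  tail over minutes-long records while leaving margin below 8x events).
  Event extent is measured with hysteresis — detections extend outward
  while the signal stays above half the threshold, so a waveform's
  duration is not collapsed to the few samples around its peak — then
  merged across gaps below 100 ms and classified by duration: spike
  < 80 ms, sharp wave 80-250 ms, long-duration discharge > 1 s,
  `"other"` between. The thresholds and classification bounds are not
  part of the inherited rule set; they are conventional in-vitro LFP
  values, fully configurable, and reported with every output, so
  absolute class rates are comparable only under a stated
  configuration.
* **Band bursts** (low gamma 30-80 Hz, high gamma/ripple 80-160 Hz):
  Hilbert envelope of the band-passed trace above 6 envelope SDs for at
  least 3 cycles of the band center.
* **Calcium synchrony**: the fraction of cells active per frame; sync
  events are local maxima above a threshold fraction, with tied
  plateaus resolved to their first frame.

All thresholds are relative to within-record statistics, so detection is
invariant to global amplitude scaling.

## Synthetic data: what it emulates and what it does not

Every analysis stage is testable against generators with exact ground
truth (`gen_pac_signal`, `gen_chaos_benchmark`, `gen_lfp_with_events`,
`gen_raster`), all pure functions of (config, seed) — identical seeds
give bit-identical output, with independent substreams derived per
component. The PAC generator builds
$\theta + \sum_f \gamma_f (1 + d\cos(\theta_{phase} - \psi_f + \text{jitter}))$
with additive white Gaussian noise and per-theta-cycle phase jitter —
the standard amplitude-modulation construction in the PAC-methods
literature. Event fixtures implant Gaussian-windowed spikes, half-sine
sharp waves, RMS-scaled sustained segments and Hann-windowed wave
packets into white noise.

These generators emulate the *features the analytics measure*, not the
recordings themselves: real organoid and depth-electrode LFPs have 1/f
backgrounds, nonstationary artifacts and multi-source mixing that white
noise does not. Passing tests therefore demonstrate that the statistics
recover known structure under controlled conditions, not that any
particular biological recording will show that structure.

## Genetic-algorithm fitting

`run_ga()` minimizes a weighted sum of squared feature errors, each
normalized by the target magnitude (or 1 near zero). The feature vector
is the minimal set the fitting story needs: monophasicity, theta band
power, theta peak frequency, theta instability K, low-gamma power.
Tournament selection (size 3), uniform crossover (rate 0.7), Gaussian
mutation with SD 10% of each parameter range (integers rounded, bounds
clipped), elitism of 2 — robust desk-scale defaults, all configurable,
with full-scale defaults of 50 individuals and 100 generations. Each
individual is evaluated by simulating the circuit and extracting
features with replicate seeds *shared across all individuals and
generations*, which makes the fitness landscape deterministic given the
GA seed: synthetic targets evaluated the same way have fitness exactly
zero at the true parameters, and runs are exactly reproducible. Diverged
simulations receive worst fitness and the run continues. The mutant
stage (`mutant_stage_fit()`) freezes everything at the control optimum
except the persistent-Na conductances and the cell counts, and places a
hard penalty (25x) on theta-power deviations beyond 20% — the
"preserved theta power" constraint.

Problem sizes used by the shipped tests and the acceptance script: the
recovery experiment uses a 6/2/3-cell base circuit, a two-parameter
space (common NaP scale, O-LM count), 20 individuals over 15
generations, one 10 s replicate per evaluation at $dt = 0.05$ ms; the
control/mutant pair uses the 4/3/6 default circuit with 12 individuals
over 6 generations. Evaluations of 10 s are the shortest that give
stable feature estimates (the instability statistic needs 1000 samples
at its 100 Hz feature-extraction rate); one replicate suffices because
the replicate seed is shared between target and candidates.

## Known limitations

* The LFP proxy is a population-mean potential, not a forward-modelled
  extracellular field; absolute powers are in model units.
* The circuit has three cell types and five pyramidal compartments;
  it is a minimal mechanistic testbed, not a full CA3.
* Discharge classification bounds are conventions, so absolute class
  rates depend on the stated configuration.
* The 0-1 test yields K near 1 for stochastic series (an AR(1) process
  is "unstable" in the same sense as a chaotic map); K separates
  periodic from aperiodic dynamics, it does not certify determinism.
* Exact signed-rank inference refuses zero or tied differences unless
  mid-ranks are requested explicitly.
* At desk-scale fitting budgets the mutant stage's recovered cell
  composition varies with the optimizer seed: most of the coupling
  disruption in this model is carried by the persistent-Na conductance,
  so the count structure is only weakly identified by short evaluations.
  How far restoring control persistent Na recovers monophasicity in a
  fitted mutant therefore depends on the composition that particular fit
  settled on.
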