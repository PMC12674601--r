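// Hodgkin-Huxley CA3 microcircuit: O-LM and basket interneurons
// (single compartment) and 5-compartment pyramidal cells, each with
// transient Na (m^3 h), persistent Na (mp), delayed-rectifier K (n^4) and
// leak currents; O-LM additionally carries h (r) and A (a*b) currents.
// Gates are advanced by exponential Euler (exact for the linear gate ODE
// at frozen V), voltages by forward Euler.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// u / (exp(u) - 1) with the removable singularity at u = 0 handled by its
// analytic limit (L'Hopital): 1 - u/2 + O(u^2).
static inline double gexp(double u) {
  if (std::fabs(u) < 1e-7) return 1.0 - u / 2.0;
  return u / std::expm1(u);
}
// u / (1 - exp(-u)) = gexp(-u)
static inline double gnexp(double u) { return gexp(-u); }

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// cell_type: 0 = OLM, 1 = basket, 2 = pyramidal
// gate ids: 0=m 1=h 2=n 3=mp 4=a 5=b 6=r (4..6 OLM only)
// v50: h-current half-activation, used by OLM gate r only.
static void gate_inf_tau(int cell, int gate, double V, double v50,
                         double &inf, double &tau) {
  double a = 0, b = 0;
  switch (cell) {
  case 0: // O-LM
    switch (gate) {
    case 0:
      a = gexp(-0.1 * (V + 38.0));
      b = 4.0 * std::exp(-(V + 65.0) / 18.0);
      break;
    case 1:
      a = 0.07 * std::exp(-(V + 63.0) / 20.0);
      b = sig((V + 33.0) / 10.0);
      break;
    case 2:
      // alpha_n = 0.018 (V-25) / (1 - exp(-(V-25)/25))
      a = 0.45 * gnexp((V - 25.0) / 25.0);
      // beta_n = 0.0036 (V-35) / (exp((V-35)/12) - 1)
      b = 0.0432 * gexp((V - 35.0) / 12.0);
      break;
    case 3:
      inf = sig((V + 52.3) / 6.8); tau = 1.0; return;
    case 4:
      inf = sig((V + 14.0) / 16.6); tau = 5.0; return;
    case 5:
      inf = 1.0 / (1.0 + std::exp((V + 71.0) / 7.3));
      tau = 1.0 / (0.000009 * std::exp(-(V - 26.0) / 18.5) +
                   0.014 / (0.2 + std::exp(-(V + 70.0) / 11.0)));
      return;
    case 6:
      inf = 1.0 / (1.0 + std::exp((V - v50) / 10.2));
      tau = 1.0 / (std::exp(-14.59 - 0.086 * V) +
                   std::exp(-1.87 + 0.0701 * V));
      return;
    default: stop("invalid O-LM gate");
    }
    break;
  case 1: // basket (fast-spiking, Wang-Buzsaki lineage, as printed)
    switch (gate) {
    case 0:
      a = gexp(-0.1 * (V + 35.0));
      b = 4.0 * std::exp(-(V + 60.0) / 18.0);
      break;
    case 1:
      a = 0.07 * std::exp(-(V + 58.0) / 20.0);
      b = sig(0.1 * (V + 28.0));
      break;
    case 2:
      a = 0.1 * gnexp(0.1 * (V + 34.0));
      b = 0.125 * std::exp(-(V + 44.0) / 80.0);
      break;
    case 3:
      inf = sig((V + 52.3) / 6.8); tau = 1.0; return;
    default: stop("invalid basket gate");
    }
    break;
  case 2: // pyramidal (Traub/Migliore lineage)
    switch (gate) {
    case 0:
      a = 1.28 * gnexp((V + 54.0) / 4.0);
      b = 1.4 * gexp((V + 27.0) / 5.0);
      break;
    case 1:
      a = 0.128 * std::exp(-(V + 50.0) / 18.0);
      b = 4.0 * sig((V + 27.0) / 5.0);
      break;
    case 2:
      a = 0.16 * gnexp((V + 52.0) / 5.0);
      b = 0.5 * std::exp(-(V + 57.0) / 40.0);
      break;
    case 3:
      inf = sig((V + 52.3) / 6.8); tau = 15.0; return;
    default: stop("invalid pyramidal gate");
    }
    break;
  default: stop("invalid cell type");
  }
  // standard HH form x_inf = alpha/(alpha+beta), tau = 1/(alpha+beta)
  tau = 1.0 / (a + b);
  inf = a * tau;
}

// [[Rcpp::export]]
NumericVector gating_kin_cpp(double V, int cell, int gate, double v50) {
  double inf, tau;
  gate_inf_tau(cell, gate, V, v50, inf, tau);
  return NumericVector::create(_["inf"] = inf, _["tau"] = tau);
}

// Membrane current sum (without applied/synaptic/axial terms), uA/cm^2.
// gates: named in fixed order m,h,n,mp[,a,b,r]
static inline double ionic_current(int cell, double V,
                                   const double *g, // gNa,gNaP,gK,gL
                                   const double *E, // ENa,EK,EL
                                   double gh, double gA, double Eh, double EA,
                                   const double *x) {
  double m = x[0], h = x[1], n = x[2], mp = x[3];
  double I = g[0] * m * m * m * h * (V - E[0]) + // INa
             g[1] * mp * (V - E[0]) +            // INaP (same reversal)
             g[2] * n * n * n * n * (V - E[1]) + // IK
             g[3] * (V - E[2]);                  // IL
  if (cell == 0) {
    I += gh * x[6] * (V - Eh) + gA * x[4] * x[5] * (V - EA);
  }
  return I;
}

// [[Rcpp::export]]
List cell_rhs_cpp(double V, NumericVector gates, int cell,
                  NumericVector params, double I_app, double I_syn,
                  double I_conn) {
  // params named: C,gNa,gNaP,gK,gL,ENa,EK,EL[,gh,gA,Eh,EA,v50]
  double C = params["C"];
  double g[4] = {(double)params["gNa"], (double)params["gNaP"],
                 (double)params["gK"], (double)params["gL"]};
  double E[3] = {(double)params["ENa"], (double)params["EK"],
                 (double)params["EL"]};
  double gh = 0, gA = 0, Eh = 0, EA = 0, v50 = -80;
  if (cell == 0) {
    gh = params["gh"]; gA = params["gA"]; Eh = params["Eh"];
    EA = params["EA"]; v50 = params["v50"];
  }
  int ng = (cell == 0) ? 7 : 4;
  if (gates.size() != ng) stop("wrong number of gates for this cell type");
  std::vector<double> x(gates.begin(), gates.end());
  double I_ion = ionic_current(cell, V, g, E, gh, gA, Eh, EA, x.data());
  double dV = (I_app - I_ion - I_syn + I_conn) / C;
  NumericVector dx(ng);
  for (int k = 0; k < ng; ++k) {
    double inf, tau;
    gate_inf_tau(cell, k, V, v50, inf, tau);
    dx[k] = (inf - x[k]) / tau;
  }
  return List::create(_["dV"] = dV, _["dgates"] = dx);
}

// ---- gating lookup tables -------------------------------------------
// inf(V) and exp(-dt/tau(V)) on a uniform grid; linear interpolation.
struct GateTable {
  double v0, dv_inv;
  std::vector<double> inf, dec;
};

static GateTable make_table(int cell, int gate, double v50, double dt) {
  GateTable t;
  const double vlo = -150.0, vhi = 100.0, dv = 0.02;
  int n = (int)((vhi - vlo) / dv) + 2;
  t.v0 = vlo; t.dv_inv = 1.0 / dv;
  t.inf.resize(n); t.dec.resize(n);
  for (int i = 0; i < n; ++i) {
    double inf, tau;
    gate_inf_tau(cell, gate, vlo + i * dv, v50, inf, tau);
    t.inf[i] = inf;
    t.dec[i] = std::exp(-dt / tau);
  }
  return t;
}

static inline void table_lookup(const GateTable &t, double V, double &inf,
                                double &dec) {
  double u = (V - t.v0) * t.dv_inv;
  int n = (int)t.inf.size();
  if (u <= 0) { inf = t.inf[0]; dec = t.dec[0]; return; }
  if (u >= n - 2) { inf = t.inf[n - 1]; dec = t.dec[n - 1]; return; }
  int i = (int)u;
  double w = u - i;
  inf = t.inf[i] + w * (t.inf[i + 1] - t.inf[i]);
  dec = t.dec[i] + w * (t.dec[i + 1] - t.dec[i]);
}

struct SynProj {
  int pre_pop, post_pop, target; // target compartment for pyramidal post
  double w, Erev, rise_inv, decay_inv;
  std::vector<double> s; // one gate per presynaptic cell
};

// [[Rcpp::export]]
List simulate_circuit_cpp(List cfg) {
  IntegerVector counts = cfg["counts"]; // OLM, basket, pyramidal
  const int nO = counts[0], nB = counts[1], nP = counts[2];
  NumericVector po = cfg["olm"], pb = cfg["basket"], pp = cfg["pyr"];
  NumericMatrix gc = cfg["gc"]; // 5x5 axial coupling, mS/cm^2 (row=post)
  DataFrame syn = as<DataFrame>(cfg["synapses"]);
  NumericVector Imean = cfg["I_mean"], Isd = cfg["I_sd"];
  const double dt = cfg["dt"];
  const long nsteps = (long)as<double>(cfg["n_steps"]);
  const int stride = cfg["rec_stride"];
  NumericVector v_init = cfg["v_init"]; // per unit (see layout below)
  const double thr = cfg["spike_thresh"];
  const int refr_steps = std::max(1, (int)std::round(
      as<double>(cfg["refractory_ms"]) / dt));
  const bool debug_gates = cfg.containsElementNamed("debug_gates")
      ? as<bool>(cfg["debug_gates"]) : false;

  const int NCOMP = 5, SOMA = 1; // basal, soma, apical1..3
  const int n_units = nO + nB + NCOMP * nP; // voltage unit layout
  const int n_cells = nO + nB + nP;
  if ((int)v_init.size() != n_units) stop("v_init length mismatch");

  double gO[4] = {po["gNa"], po["gNaP"], po["gK"], po["gL"]};
  double EO[3] = {po["ENa"], po["EK"], po["EL"]};
  double gB[4] = {pb["gNa"], pb["gNaP"], pb["gK"], pb["gL"]};
  double EB[3] = {pb["ENa"], pb["EK"], pb["EL"]};
  double gP[4] = {pp["gNa"], pp["gNaP"], pp["gK"], pp["gL"]};
  double EP[3] = {pp["ENa"], pp["EK"], pp["EL"]};
  const double CO = po["C"], CB = pb["C"], CP = pp["C"];
  const double gh = po["gh"], gA = po["gA"], Eh = po["Eh"], EA = po["EA"];
  const double v50 = po["v50"];

  // gating tables: OLM 7, basket 4, pyramidal 4
  std::vector<GateTable> tabO, tabB, tabP;
  for (int k = 0; k < 7; ++k) tabO.push_back(make_table(0, k, v50, dt));
  for (int k = 0; k < 4; ++k) tabB.push_back(make_table(1, k, v50, dt));
  for (int k = 0; k < 4; ++k) tabP.push_back(make_table(2, k, v50, dt));

  // state
  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> xO(7 * nO), xB(4 * nB), xP(4 * NCOMP * nP);
  for (int i = 0; i < nO; ++i)
    for (int k = 0; k < 7; ++k) {
      double inf, tau; gate_inf_tau(0, k, V[i], v50, inf, tau);
      xO[7 * i + k] = inf;
    }
  for (int i = 0; i < nB; ++i)
    for (int k = 0; k < 4; ++k) {
      double inf, tau; gate_inf_tau(1, k, V[nO + i], v50, inf, tau);
      xB[4 * i + k] = inf;
    }
  for (int i = 0; i < NCOMP * nP; ++i)
    for (int k = 0; k < 4; ++k) {
      double inf, tau; gate_inf_tau(2, k, V[nO + nB + i], v50, inf, tau);
      xP[4 * i + k] = inf;
    }

  // synapse projections
  IntegerVector s_pre = syn["pre"], s_post = syn["post"],
                s_tgt = syn["target"];
  NumericVector s_w = syn["weight"], s_E = syn["E_rev"], s_r = syn["rise"],
                s_d = syn["decay"];
  std::vector<SynProj> proj;
  const int npre_pop[3] = {nO, nB, nP};
  for (int j = 0; j < s_pre.size(); ++j) {
    if (npre_pop[s_pre[j]] == 0 || npre_pop[s_post[j]] == 0) continue;
    SynProj p;
    p.pre_pop = s_pre[j]; p.post_pop = s_post[j]; p.target = s_tgt[j];
    p.w = s_w[j]; p.Erev = s_E[j];
    p.rise_inv = 1.0 / s_r[j]; p.decay_inv = 1.0 / s_d[j];
    p.s.assign(npre_pop[p.pre_pop], 0.0);
    proj.push_back(p);
  }

  // presynaptic (soma for pyramidal) voltage index of cell i in pop
  auto pre_vidx = [&](int pop, int i) {
    return pop == 0 ? i : pop == 1 ? nO + i : nO + nB + NCOMP * i + SOMA;
  };

  // recording
  const long n_rec = nsteps / stride;
  NumericMatrix Vrec(n_rec, n_units);
  std::vector<std::vector<int>> spikes(n_cells);
  std::vector<int> last_spike(n_cells, -refr_steps - 1);
  std::vector<double> v_prev_cell(n_cells);
  for (int c = 0; c < n_cells; ++c)
    v_prev_cell[c] = V[c < nO + nB ? c : nO + nB + NCOMP * (c - nO - nB) + SOMA];

  std::vector<double> Isyn(n_units, 0.0);
  const double noise_scale = 1.0 / std::sqrt(dt);
  RNGScope rng;

  for (long step = 0; step < nsteps; ++step) {
    // synaptic currents onto each unit
    std::fill(Isyn.begin(), Isyn.end(), 0.0);
    for (auto &p : proj) {
      double stot = 0.0;
      for (double sv : p.s) stot += sv;
      double gsum = p.w * stot;  // weight is per presynaptic cell
      int npost = npre_pop[p.post_pop];
      for (int i = 0; i < npost; ++i) {
        int vi = p.post_pop == 2 ? nO + nB + NCOMP * i + p.target
                                 : pre_vidx(p.post_pop, i);
        Isyn[vi] += gsum * (V[vi] - p.Erev);
      }
    }

    // voltage updates (forward Euler); noise drawn in fixed order
    for (int i = 0; i < nO; ++i) {
      double Iapp = Imean[0] + (Isd[0] > 0 ?
          Isd[0] * noise_scale * R::norm_rand() : 0.0);
      double Iion = ionic_current(0, V[i], gO, EO, gh, gA, Eh, EA,
                                  &xO[7 * i]);
      V[i] += dt * (Iapp - Iion - Isyn[i]) / CO;
    }
    for (int i = 0; i < nB; ++i) {
      int vi = nO + i;
      double Iapp = Imean[1] + (Isd[1] > 0 ?
          Isd[1] * noise_scale * R::norm_rand() : 0.0);
      double Iion = ionic_current(1, V[vi], gB, EB, 0, 0, 0, 0, &xB[4 * i]);
      V[vi] += dt * (Iapp - Iion - Isyn[vi]) / CB;
    }
    for (int i = 0; i < nP; ++i) {
      double Iapp_soma = Imean[2] + (Isd[2] > 0 ?
          Isd[2] * noise_scale * R::norm_rand() : 0.0);
      double dV[NCOMP];
      for (int k = 0; k < NCOMP; ++k) {
        int vi = nO + nB + NCOMP * i + k;
        double Iion = ionic_current(2, V[vi], gP, EP, 0, 0, 0, 0,
                                    &xP[4 * (NCOMP * i + k)]);
        double Iconn = 0.0;
        for (int j = 0; j < NCOMP; ++j)
          if (gc(k, j) != 0.0)
            Iconn += gc(k, j) * (V[nO + nB + NCOMP * i + j] - V[vi]);
        double Iapp = (k == SOMA) ? Iapp_soma : 0.0;
        dV[k] = (Iapp - Iion - Isyn[vi] + Iconn) / CP;
      }
      for (int k = 0; k < NCOMP; ++k)
        V[nO + nB + NCOMP * i + k] += dt * dV[k];
    }

    // gate updates (exponential Euler at the updated V), clamped to [0,1]
    for (int i = 0; i < nO; ++i)
      for (int k = 0; k < 7; ++k) {
        double inf, dec; table_lookup(tabO[k], V[i], inf, dec);
        double &x = xO[7 * i + k];
        x = inf + (x - inf) * dec;
        if (x < 0) x = 0; else if (x > 1) x = 1;
      }
    for (int i = 0; i < nB; ++i)
      for (int k = 0; k < 4; ++k) {
        double inf, dec; table_lookup(tabB[k], V[nO + i], inf, dec);
        double &x = xB[4 * i + k];
        x = inf + (x - inf) * dec;
        if (x < 0) x = 0; else if (x > 1) x = 1;
      }
    for (int i = 0; i < NCOMP * nP; ++i)
      for (int k = 0; k < 4; ++k) {
        double inf, dec; table_lookup(tabP[k], V[nO + nB + i], inf, dec);
        double &x = xP[4 * i + k];
        x = inf + (x - inf) * dec;
        if (x < 0) x = 0; else if (x > 1) x = 1;
      }
    if (debug_gates) {
      for (double x : xO) if (x < 0 || x > 1) stop("gate out of [0,1]");
      for (double x : xB) if (x < 0 || x > 1) stop("gate out of [0,1]");
      for (double x : xP) if (x < 0 || x > 1) stop("gate out of [0,1]");
    }

    // synaptic gates (exponential Euler, exact at frozen presyn V)
    for (auto &p : proj) {
      for (size_t i = 0; i < p.s.size(); ++i) {
        double F = sig(V[pre_vidx(p.pre_pop, (int)i)] / 2.0);
        double A = p.rise_inv * F;
        double B = A + p.decay_inv;
        double sinf = A / B;
        p.s[i] = sinf + (p.s[i] - sinf) * std::exp(-B * dt);
      }
    }

    // spike detection: upward crossing of threshold with refractory
    for (int c = 0; c < n_cells; ++c) {
      int vi = c < nO + nB ? c : nO + nB + NCOMP * (c - nO - nB) + SOMA;
      double v = V[vi];
      if (v_prev_cell[c] < thr && v >= thr &&
          (int)step - last_spike[c] > refr_steps) {
        spikes[c].push_back((int)step);
        last_spike[c] = (int)step;
      }
      v_prev_cell[c] = v;
    }

    // divergence check
    for (int u = 0; u < n_units; ++u)
      if (!std::isfinite(V[u]) || std::fabs(V[u]) > 500.0)
        stop("simulation diverged at step %ld, unit %d (V=%g)",
             step, u + 1, V[u]);

    if ((step + 1) % stride == 0) {
      long r = (step + 1) / stride - 1;
      for (int u = 0; u < n_units; ++u) Vrec(r, u) = V[u];
    }
  }

  List spk(n_cells);
  for (int c = 0; c < n_cells; ++c) spk[c] = wrap(spikes[c]);
  return List::create(_["V"] = Vrec, _["spike_steps"] = spk,
                      _["n_steps"] = (double)nsteps);
}
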