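// Fixed-step integrator for compartmental Hodgkin-Huxley network models.
//
// Scheme: exponential Euler for gating variables and the calcium pool,
// backward (implicit) Euler for the voltage equation with channel and synaptic
// conductances frozen at the updated gate values.  The voltage system is a
// tree per cell and is solved exactly with Hines elimination (nodes are
// required to arrive parent-before-child).
//
// Unit system: mV, ms, nA, uS, MOhm, nF, um.  uS * mV = nA; MOhm * nF = ms.
// Dipole output in nAm: nA * um * 1e-6.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline double safeexp(double x) {
  if (x > 50.0) x = 50.0;
  if (x < -50.0) x = -50.0;
  return std::exp(x);
}

// x / (exp(x / y) - 1), stable near x = 0
inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct Gates {
  // fixed layout per node
  double na_m, na_h, k_n, kdr_n, km_m, ca_m, cat_m, cat_h, h_q, kca_m;
};

struct Rates { double inf, tau; };

inline Rates rate_na_m(double v) {
  double a = 0.32 * vtrap(-(v + 54.0), 4.0);
  double b = 0.28 * vtrap(v + 27.0, 5.0);
  Rates r; r.tau = 1.0 / (a + b); r.inf = a * r.tau; return r;
}
inline Rates rate_na_h(double v) {
  double a = 0.128 * safeexp(-(v + 50.0) / 18.0);
  double b = 4.0 / (1.0 + safeexp(-(v + 27.0) / 5.0));
  Rates r; r.tau = 1.0 / (a + b); r.inf = a * r.tau; return r;
}
inline Rates rate_k_n(double v) {
  double a = 0.032 * vtrap(-(v + 52.0), 5.0);
  double b = 0.5 * safeexp(-(v + 57.0) / 40.0);
  Rates r; r.tau = 1.0 / (a + b); r.inf = a * r.tau; return r;
}
inline Rates rate_kdr_n(double v) {
  Rates r; r.inf = 1.0 / (1.0 + safeexp(-(v + 46.3) / 3.0)); r.tau = 3.5; return r;
}
inline Rates rate_km_m(double v) {
  Rates r;
  r.inf = 1.0 / (1.0 + safeexp(-(v + 35.0) / 10.0));
  r.tau = 1000.0 / (3.3 * (safeexp((v + 35.0) / 20.0) + safeexp(-(v + 35.0) / 20.0)));
  return r;
}
inline Rates rate_ca_m(double v) {
  double a = 1.6 / (1.0 + safeexp(-0.072 * (v - 5.0)));
  double b = 0.02 * vtrap(v + 8.9, 5.0);
  Rates r; r.tau = 1.0 / (a + b); r.inf = a * r.tau; return r;
}
inline Rates rate_cat_m(double v) {
  Rates r;
  r.inf = 1.0 / (1.0 + safeexp(-(v + 57.0) / 6.2));
  r.tau = 0.612 + 1.0 / (safeexp(-(v + 132.0) / 16.7) + safeexp((v + 16.8) / 18.2));
  return r;
}
inline Rates rate_cat_h(double v) {
  Rates r;
  r.inf = 1.0 / (1.0 + safeexp((v + 81.0) / 4.0));
  if (v < -81.0) r.tau = safeexp((v + 467.0) / 66.6);
  else r.tau = 28.0 + safeexp(-(v + 22.0) / 10.5);
  return r;
}
inline Rates rate_h_q(double v) {
  Rates r;
  r.inf = 1.0 / (1.0 + safeexp((v + 81.0) / 8.0));
  r.tau = 1.0 / (safeexp(-14.59 - 0.086 * v) + safeexp(-1.87 + 0.0701 * v));
  if (r.tau < 1.0) r.tau = 1.0;
  return r;
}
inline Rates rate_kca_m(double ca) {
  double a = 0.01 * ca;
  double b = 0.02;
  Rates r; r.tau = 1.0 / (a + b); r.inf = a * r.tau;
  if (r.tau < 0.5) r.tau = 0.5;
  return r;
}

// Wang-Buzsaki fast-spiking interneuron kinetics (phi = 5)
inline double wb_minf(double v) {
  double a = 0.1 * vtrap(-(v + 35.0), 10.0);
  double b = 4.0 * safeexp(-(v + 60.0) / 18.0);
  return a / (a + b);
}
inline Rates rate_wb_h(double v) {
  double a = 5.0 * 0.07 * safeexp(-(v + 58.0) / 20.0);
  double b = 5.0 / (1.0 + safeexp(-0.1 * (v + 28.0)));
  Rates r; r.tau = 1.0 / (a + b); r.inf = a * r.tau; return r;
}
inline Rates rate_wb_n(double v) {
  double a = 5.0 * 0.01 * vtrap(-(v + 34.0), 10.0);
  double b = 5.0 * 0.125 * safeexp(-(v + 44.0) / 80.0);
  Rates r; r.tau = 1.0 / (a + b); r.inf = a * r.tau; return r;
}

inline void gate_step(double &x, const Rates &r, double dt) {
  x = r.inf + (x - r.inf) * std::exp(-dt / r.tau);
}

struct Ev { int node; int cls; double w; };

} // namespace

// Channel column order in `g`:
// 0 na, 1 k, 2 leak, 3 kdr, 4 km, 5 ca, 6 h, 7 cat, 8 kca
// [[Rcpp::export(name = ".engine_simulate")]]
List engine_simulate(List net, List run) {
  const IntegerVector parent = net["parent"];
  const NumericVector r_ax   = net["r_ax"];
  const NumericVector cap    = net["cap"];
  const NumericVector zproj  = net["z"];
  const NumericMatrix g      = net["g"];
  const NumericVector e_leak = net["e_leak"];
  const NumericVector vshift = net["vshift"]; // spike-current kinetics offset, mV
  const NumericVector fs = net["fs"]; // 1 = Wang-Buzsaki fast-spiking na/k kinetics
  const NumericVector e_rev  = net["e_rev"];   // na, k, ca, h
  const NumericVector ca_factor = net["ca_factor"]; // 0 => no pool
  const double ca_tau = as<double>(net["ca_tau"]);
  const double ca0    = as<double>(net["ca0"]);
  const IntegerVector cell_of  = net["cell"];     // 0-based
  const IntegerVector soma_node = net["soma_node"]; // per cell, 0-based
  const IntegerVector cell_layer = net["cell_layer"]; // per cell, 0-based
  const LogicalVector cell_is_pyr = net["cell_is_pyr"];
  const int n_layers = as<int>(net["n_layers"]);
  const CharacterVector node_label = net["node_label"];

  const NumericVector syn_tau_r = net["syn_tau_r"];
  const NumericVector syn_tau_d = net["syn_tau_d"];
  const NumericVector syn_e     = net["syn_e"];
  const IntegerVector gaba_classes = net["gaba_classes"]; // 0-based class ids

  const IntegerVector conn_pre   = net["conn_pre"];
  const IntegerVector conn_node  = net["conn_node"];
  const IntegerVector conn_class = net["conn_class"];
  const NumericVector conn_w     = net["conn_w"];
  const IntegerVector conn_delay = net["conn_delay_steps"];

  const IntegerVector exo_step  = run["exo_step"];
  const IntegerVector exo_node  = run["exo_node"];
  const IntegerVector exo_class = run["exo_class"];
  const NumericVector exo_w     = run["exo_w"];

  const NumericVector iapp = run["iapp"];
  const IntegerVector inj_node = run["inj_node"];
  const NumericMatrix inj_I = run["inj_I"]; // (n_steps+1) x length(inj_node)

  const double dt = as<double>(run["dt"]);
  const int n_steps = as<int>(run["n_steps"]);
  const NumericVector v_init = run["v_init"];
  const IntegerVector rec_nodes = run["record_nodes"];
  const bool record_soma = as<bool>(run["record_soma"]);
  const bool record_gaba = as<bool>(run["record_gaba"]);
  const double thresh = as<double>(run["spike_threshold"]);
  const double refrac = as<double>(run["refractory"]);

  const int N = parent.size();
  const int n_cells = soma_node.size();
  const int n_cls = syn_tau_r.size();

  // synapse normalization factors and per-step decay multipliers
  std::vector<double> syn_f(n_cls), dec_r(n_cls), dec_d(n_cls);
  for (int c = 0; c < n_cls; ++c) {
    double tr = syn_tau_r[c], td = syn_tau_d[c];
    double tp = (td * tr / (td - tr)) * std::log(td / tr);
    syn_f[c] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    dec_r[c] = std::exp(-dt / tr);
    dec_d[c] = std::exp(-dt / td);
  }
  std::vector<bool> is_gaba(n_cls, false);
  for (int i = 0; i < gaba_classes.size(); ++i) is_gaba[gaba_classes[i]] = true;

  // synaptic state: rise (A) and decay (B) per node per class
  std::vector<double> synA((size_t)N * n_cls, 0.0), synB((size_t)N * n_cls, 0.0);

  // event queue by step
  std::vector<std::vector<Ev>> queue(n_steps + 2);
  for (int i = 0; i < exo_step.size(); ++i) {
    int s = exo_step[i];
    if (s >= 0 && s <= n_steps) queue[s].push_back(Ev{exo_node[i], exo_class[i], exo_w[i]});
  }

  // connections grouped by presynaptic cell
  std::vector<std::vector<int>> conn_by_pre(n_cells);
  for (int i = 0; i < conn_pre.size(); ++i) conn_by_pre[conn_pre[i]].push_back(i);

  // state
  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<Gates> gs(N);
  std::vector<double> ca(N, ca0);
  for (int i = 0; i < N; ++i) {
    double vi = v[i];
    double vsh = vi + vshift[i];
    if (fs[i] > 0) {
      gs[i].na_m = wb_minf(vsh);      gs[i].na_h = rate_wb_h(vsh).inf;
      gs[i].k_n = rate_wb_n(vsh).inf;
    } else {
      gs[i].na_m = rate_na_m(vsh).inf;  gs[i].na_h = rate_na_h(vsh).inf;
      gs[i].k_n = rate_k_n(vsh).inf;
    }
    gs[i].kdr_n = rate_kdr_n(vi).inf;
    gs[i].km_m = rate_km_m(vi).inf;  gs[i].ca_m = rate_ca_m(vi).inf;
    gs[i].cat_m = rate_cat_m(vi).inf; gs[i].cat_h = rate_cat_h(vi).inf;
    gs[i].h_q = rate_h_q(vi).inf;    gs[i].kca_m = rate_kca_m(ca0).inf;
  }

  // outputs
  NumericMatrix dipole(n_steps + 1, n_layers);
  NumericMatrix gaba_cur;
  if (record_gaba) gaba_cur = NumericMatrix(n_steps + 1, n_layers);
  NumericMatrix soma_v;
  if (record_soma) soma_v = NumericMatrix(n_steps + 1, n_cells);
  NumericMatrix v_rec(rec_nodes.size() > 0 ? n_steps + 1 : 0, rec_nodes.size());
  std::vector<std::vector<double>> spikes(n_cells);
  std::vector<double> last_spike(n_cells, -1e9);
  std::vector<double> prev_soma(n_cells);
  for (int c = 0; c < n_cells; ++c) prev_soma[c] = v[soma_node[c]];

  // per-cell layer/pyr lookup per node
  std::vector<int> node_layer(N);
  std::vector<bool> node_pyr(N);
  for (int i = 0; i < N; ++i) {
    node_layer[i] = cell_layer[cell_of[i]];
    node_pyr[i] = cell_is_pyr[cell_of[i]];
  }

  auto write_dipole = [&](int row) {
    for (int i = 0; i < N; ++i) {
      if (parent[i] < 0 || !node_pyr[i] || zproj[i] == 0.0) continue;
      // axial current parent -> node, positive toward the pia when z > 0
      double I = (v[parent[i]] - v[i]) / r_ax[i];
      dipole(row, node_layer[i]) += I * zproj[i] * 1e-6;
    }
  };
  auto write_gaba = [&](int row) {
    for (int c = 0; c < n_cells; ++c) {
      if (!cell_is_pyr[c]) continue;
      int i = soma_node[c];
      for (int cl = 0; cl < n_cls; ++cl) {
        if (!is_gaba[cl]) continue;
        double gsyn = syn_f[cl] * (synB[(size_t)i * n_cls + cl] - synA[(size_t)i * n_cls + cl]);
        if (gsyn > 0) gaba_cur(row, cell_layer[c]) += gsyn * (v[i] - syn_e[cl]);
      }
    }
  };

  write_dipole(0);
  if (record_gaba) write_gaba(0);
  if (record_soma) for (int c = 0; c < n_cells; ++c) soma_v(0, c) = v[soma_node[c]];
  for (int j = 0; j < rec_nodes.size(); ++j) v_rec(0, j) = v[rec_nodes[j]];

  std::vector<double> d(N), rhs(N);
  const double ena = e_rev[0], ek = e_rev[1], eca = e_rev[2], eh = e_rev[3];

  for (int s = 0; s < n_steps; ++s) {
    // deliver events due at this step
    for (const Ev &e : queue[s]) {
      synA[(size_t)e.node * n_cls + e.cls] += e.w;
      synB[(size_t)e.node * n_cls + e.cls] += e.w;
    }

    // assemble linear system with gates advanced by exponential Euler
    for (int i = 0; i < N; ++i) {
      double vi = v[i];
      double gsum = 0.0, isum = iapp[i];
      Gates &G = gs[i];

      double vs = vi + vshift[i]; // na/k gating sees shifted voltage
      if (fs[i] > 0) {
        if (g(i, 0) > 0) { // na, WB: m instantaneous
          gate_step(G.na_h, rate_wb_h(vs), dt);
          double m = wb_minf(vs);
          double gg = g(i, 0) * m * m * m * G.na_h;
          gsum += gg; isum += gg * ena;
        }
        if (g(i, 1) > 0) { // k, WB: n^4
          gate_step(G.k_n, rate_wb_n(vs), dt);
          double n2 = G.k_n * G.k_n;
          double gg = g(i, 1) * n2 * n2;
          gsum += gg; isum += gg * ek;
        }
      } else {
      if (g(i, 0) > 0) { // na
        gate_step(G.na_m, rate_na_m(vs), dt);
        gate_step(G.na_h, rate_na_h(vs), dt);
        double gg = g(i, 0) * G.na_m * G.na_m * G.na_m * G.na_h;
        gsum += gg; isum += gg * ena;
      }
      if (g(i, 1) > 0) { // k
        gate_step(G.k_n, rate_k_n(vs), dt);
        double n2 = G.k_n * G.k_n;
        double gg = g(i, 1) * n2 * n2;
        gsum += gg; isum += gg * ek;
      }
      }
      if (g(i, 2) > 0) { // leak
        gsum += g(i, 2); isum += g(i, 2) * e_leak[i];
      }
      if (g(i, 3) > 0) { // kdr
        gate_step(G.kdr_n, rate_kdr_n(vi), dt);
        double gg = g(i, 3) * G.kdr_n;
        gsum += gg; isum += gg * ek;
      }
      if (g(i, 4) > 0) { // km
        gate_step(G.km_m, rate_km_m(vi), dt);
        double gg = g(i, 4) * G.km_m;
        gsum += gg; isum += gg * ek;
      }
      double i_ca_now = 0.0;
      if (g(i, 5) > 0) { // ca (HVA)
        gate_step(G.ca_m, rate_ca_m(vi), dt);
        double gg = g(i, 5) * G.ca_m * G.ca_m;
        gsum += gg; isum += gg * eca;
        i_ca_now += gg * (vi - eca);
      }
      if (g(i, 6) > 0) { // h
        gate_step(G.h_q, rate_h_q(vi), dt);
        double gg = g(i, 6) * G.h_q;
        gsum += gg; isum += gg * eh;
      }
      if (g(i, 7) > 0) { // cat
        gate_step(G.cat_m, rate_cat_m(vi), dt);
        gate_step(G.cat_h, rate_cat_h(vi), dt);
        double gg = g(i, 7) * G.cat_m * G.cat_m * G.cat_h;
        gsum += gg; isum += gg * eca;
        i_ca_now += gg * (vi - eca);
      }
      if (ca_factor[i] > 0) { // calcium pool (exp Euler on relaxation)
        double target = ca0 - ca_factor[i] * i_ca_now * ca_tau;
        ca[i] = target + (ca[i] - target) * std::exp(-dt / ca_tau);
        if (ca[i] < 0) ca[i] = 0;
      }
      if (g(i, 8) > 0) { // kca
        gate_step(G.kca_m, rate_kca_m(ca[i]), dt);
        double gg = g(i, 8) * G.kca_m;
        gsum += gg; isum += gg * ek;
      }

      // synapses
      for (int cl = 0; cl < n_cls; ++cl) {
        size_t k = (size_t)i * n_cls + cl;
        if (synA[k] > 0 || synB[k] > 0) {
          synA[k] *= dec_r[cl];
          synB[k] *= dec_d[cl];
          double gg = syn_f[cl] * (synB[k] - synA[k]);
          if (gg > 0) { gsum += gg; isum += gg * syn_e[cl]; }
          if (synB[k] < 1e-14 && synA[k] < 1e-14) { synA[k] = 0; synB[k] = 0; }
        }
      }

      d[i] = cap[i] / dt + gsum;
      rhs[i] = cap[i] / dt * vi + isum;
    }

    // injected currents
    for (int j = 0; j < inj_node.size(); ++j) rhs[inj_node[j]] += inj_I(s, j);

    // axial coupling (symmetric) and Hines elimination
    for (int i = 0; i < N; ++i) {
      if (parent[i] >= 0) {
        double ga = 1.0 / r_ax[i];
        d[i] += ga; d[parent[i]] += ga;
      }
    }
    for (int i = N - 1; i >= 0; --i) {
      int p = parent[i];
      if (p < 0) continue;
      double ga = 1.0 / r_ax[i];
      double f = -ga / d[i];
      d[p] -= f * -ga;
      rhs[p] -= f * rhs[i];
    }
    for (int i = 0; i < N; ++i) {
      int p = parent[i];
      if (p < 0) v[i] = rhs[i] / d[i];
      else v[i] = (rhs[i] + (1.0 / r_ax[i]) * v[p]) / d[i];
    }

    double tnew = (s + 1) * dt;

    // stability check
    for (int i = 0; i < N; ++i) {
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 200.0) {
        stop("numerical instability at t = %.3f ms in compartment '%s' (v = %g mV)",
             tnew, std::string(node_label[i]).c_str(), v[i]);
      }
    }

    // spike detection on somata, schedule synaptic events
    for (int c = 0; c < n_cells; ++c) {
      int i = soma_node[c];
      double v_prev = prev_soma[c];
      prev_soma[c] = v[i];
      if (v_prev < thresh && v[i] >= thresh && tnew - last_spike[c] >= refrac) {
        last_spike[c] = tnew;
        spikes[c].push_back(tnew);
        for (int ci : conn_by_pre[c]) {
          int due = s + conn_delay[ci];
          if (due <= n_steps) queue[due].push_back(Ev{conn_node[ci], conn_class[ci], conn_w[ci]});
        }
      }
    }

    // record
    write_dipole(s + 1);
    if (record_gaba) write_gaba(s + 1);
    if (record_soma) for (int c = 0; c < n_cells; ++c) soma_v(s + 1, c) = v[soma_node[c]];
    for (int j = 0; j < rec_nodes.size(); ++j) v_rec(s + 1, j) = v[rec_nodes[j]];

    if (s % 4000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector tgrid(n_steps + 1);
  for (int s = 0; s <= n_steps; ++s) tgrid[s] = s * dt;

  List spk(n_cells);
  for (int c = 0; c < n_cells; ++c) spk[c] = NumericVector(spikes[c].begin(), spikes[c].end());

  return List::create(
    _["time"] = tgrid,
    _["dipole"] = dipole,
    _["spikes"] = spk,
    _["soma_v"] = record_soma ? (SEXP)soma_v : R_NilValue,
    _["v"] = v_rec,
    _["gaba_current"] = record_gaba ? (SEXP)gaba_cur : R_NilValue);
}
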