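// Integrate-and-fire avalanche dynamics on a fixed directed network.
//
// Conventions: membrane potentials v rest at 0 and a neuron fires when
// v >= vc with its refractory flag clear; all supra-threshold neurons in a
// timestep fire synchronously and their contributions v_i * u_i * g_ij
// (sign flipped for inhibitory senders) are summed at the targets before
// the next threshold check.  The external drive delta_v acts only on
// quiescent timesteps (separation of time scales); synaptic resources u
// recover by delta_u_rec, capped at 1, between avalanches.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Run the dynamics for a budget of timesteps or avalanches.
//
// edge_ptr: CSR offsets (length N+1, 0-based); edge_tgt: 0-based targets;
// edge_g: strengths, modified in place semantics via returned copy.
// Budgets are doubles so callers can pass > 2^31; exactly one of
// n_timesteps / n_avalanches must be positive (the other 0).
// [[Rcpp::export]]
List cpp_run_recording(IntegerVector edge_ptr, IntegerVector edge_tgt,
                       NumericVector edge_g_in, LogicalVector inhibitory,
                       NumericVector v_in, NumericVector u_in,
                       double vc, double delta_u, double delta_u_rec,
                       double delta_v, double beta, double g_min,
                       double n_timesteps, double n_avalanches,
                       bool plasticity, bool stop_at_gmin,
                       double t_start, int seed) {
  const int N = inhibitory.size();
  const int Ns = edge_tgt.size();
  std::vector<double> g(edge_g_in.begin(), edge_g_in.end());
  std::vector<double> v(v_in.begin(), v_in.end());
  std::vector<double> u(u_in.begin(), u_in.end());
  std::vector<char> refr(N, 0);
  std::vector<double> dv(N, 0.0);

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, N - 1);

  std::vector<int> spike_t, spike_id;
  std::vector<double> av_start, av_dur, av_size;

  long long t = static_cast<long long>(t_start);
  const long long t_max = n_timesteps > 0
    ? static_cast<long long>(t_start + n_timesteps) : -1;
  const long long av_max = n_avalanches > 0
    ? static_cast<long long>(n_avalanches) : -1;
  long long n_av = 0;
  bool gmin_hit = false;
  bool truncated = false;

  // initial supra-threshold neurons (callers may pre-charge states)
  auto any_supra = [&]() {
    for (int i = 0; i < N; ++i) if (v[i] >= vc) return true;
    return false;
  };

  if (n_timesteps <= 0 && n_avalanches <= 0) {
    // zero budget: empty outputs
  } else while (true) {
    if (av_max >= 0 && n_av >= av_max) break;
    if (t_max >= 0 && t >= t_max) break;

    if (!any_supra()) {
      // quiescent timestep: clear refractoriness, drive one random neuron
      std::fill(refr.begin(), refr.end(), 0);
      v[pick(rng)] += delta_v;
      ++t;
      continue;
    }

    // --- avalanche ---
    long long start = t;
    long long dur = 0, size = 0;
    double sum_dg = 0.0;
    std::vector<int> firers;
    while (true) {
      firers.clear();
      bool supra_refr = false;
      for (int i = 0; i < N; ++i) {
        if (v[i] >= vc) {
          if (!refr[i]) firers.push_back(i); else supra_refr = true;
        }
      }
      if (firers.empty()) {
        if (!supra_refr) break;           // all v < vc: avalanche over
        // only refractory neurons are supra-threshold: time advances,
        // flags clear, they fire next step
        std::fill(refr.begin(), refr.end(), 0);
        ++t; ++dur;
        if (t_max >= 0 && t >= t_max) { truncated = true; break; }
        continue;
      }
      // contributions from all synchronous firers, computed from v(t)
      for (int idx : firers) {
        const double amp = v[idx] * u[idx];
        const double sgn = inhibitory[idx] ? -1.0 : 1.0;
        for (int e = edge_ptr[idx]; e < edge_ptr[idx + 1]; ++e) {
          const double d = sgn * amp * g[e];
          dv[edge_tgt[e]] += d;
          if (plasticity) {
            const double dgj = beta * d;
            sum_dg += dgj;
            g[e] += dgj;
            if (g[e] > 1.0) g[e] = 1.0;
            if (g[e] < g_min) g[e] = g_min;
          }
        }
        spike_t.push_back(static_cast<int>(t));
        spike_id.push_back(idx);
      }
      size += static_cast<long long>(firers.size());
      std::fill(refr.begin(), refr.end(), 0);
      for (int j = 0; j < N; ++j) {
        if (dv[j] != 0.0) { v[j] += dv[j]; dv[j] = 0.0; }
      }
      for (int idx : firers) {
        u[idx] *= (1.0 - delta_u);
        v[idx] = 0.0;
        refr[idx] = 1;
      }
      ++t; ++dur;
      if (t_max >= 0 && t >= t_max) { truncated = true; break; }
      if (dur > 2000000)
        stop("avalanche exceeded 2e6 timesteps: the dynamics appear "
             "non-terminating at these parameters");
    }
    if (size > 0) {
      av_start.push_back(static_cast<double>(start));
      av_dur.push_back(static_cast<double>(dur));
      av_size.push_back(static_cast<double>(size));
      ++n_av;
    }
    // between-avalanche recovery of synaptic resources, capped at 1
    for (int i = 0; i < N; ++i) {
      u[i] += delta_u_rec;
      if (u[i] > 1.0) u[i] = 1.0;
    }
    if (plasticity && Ns > 0) {
      const double m = sum_dg / static_cast<double>(Ns);
      for (int e = 0; e < Ns; ++e) {
        g[e] -= m;
        if (g[e] > 1.0) g[e] = 1.0;
        if (g[e] <= g_min) { g[e] = g_min; gmin_hit = true; }
      }
      if (stop_at_gmin && gmin_hit) break;
    }
    if (truncated) break;
  }

  return List::create(
    _["spike_t"] = wrap(spike_t),
    _["spike_id"] = wrap(spike_id),
    _["av_start"] = wrap(av_start),
    _["av_dur"] = wrap(av_dur),
    _["av_size"] = wrap(av_size),
    _["g"] = wrap(g),
    _["v"] = wrap(v),
    _["u"] = wrap(u),
    _["t_end"] = static_cast<double>(t),
    _["n_avalanches"] = static_cast<double>(n_av),
    _["gmin_hit"] = gmin_hit,
    _["truncated"] = truncated);
}
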