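// K-pairwise generalized Ising model: H(s) = -sum_i h_i s_i
//   - sum_{i<j} J_ij s_i s_j - sum_K V_K delta(K, K'(s)),  s_i = +/-1,
// with K'(s) the number of up spins.  Sampling follows P(s,T) = exp(-H/T)/Z
// with H always evaluated at the T=1 parameters.
//
// Metropolis statistics are exact per-attempt averages: scalar observables
// (H, M, K histogram, per-spin means) are accumulated lazily over the
// piecewise-constant intervals between accepted flips; pair and triple
// products are accumulated every `pair_stride` attempts (an unbiased
// subsample; stride 1 recovers the every-attempt estimator).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct ChainSums {
  std::vector<double> s_sum;      // per-spin occupancy sums
  std::vector<double> pk_sum;     // histogram over K (per attempt)
  double H_sum = 0, H2_sum = 0, M_sum = 0, M2_sum = 0;
  std::vector<double> pair_sum;   // strided
  std::vector<double> trip_sum;   // strided
  double n_attempts = 0;
  double n_strided = 0;
};

// One Metropolis pass over `n_attempts` single-spin-flip attempts.
// Statistics (if collect) are per-attempt averages of the post-update state.
void run_metropolis(const double *h, const double *Jm, const double *V,
                    int N, double T, double n_attempts,
                    std::vector<int> &s, std::mt19937_64 &rng,
                    bool collect, int pair_stride,
                    const int *triples, int n_triples,
                    ChainSums *out,
                    IntegerMatrix *raster, int raster_thin, int *raster_row) {
  std::uniform_real_distribution<double> runif01(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, N - 1);

  // current energy, K
  double H = 0.0;
  int K = 0;
  for (int i = 0; i < N; ++i) {
    H -= h[i] * s[i];
    if (s[i] > 0) ++K;
    for (int j = i + 1; j < N; ++j) H -= Jm[i + (size_t)j * N] * s[i] * s[j];
  }
  H -= V[K];

  const long long n_att = static_cast<long long>(n_attempts);
  // lazy accumulators
  std::vector<long long> last_i;
  long long last_g = 0;
  if (collect) {
    last_i.assign(N, 0);
    out->s_sum.assign(N, 0.0);
    out->pk_sum.assign(N + 1, 0.0);
    if (pair_stride > 0) out->pair_sum.assign((size_t)N * (N - 1) / 2, 0.0);
    if (n_triples > 0) out->trip_sum.assign(n_triples, 0.0);
    out->n_attempts = static_cast<double>(n_att);
  }

  for (long long a = 1; a <= n_att; ++a) {
    const int i = pick(rng);
    double loc = h[i];
    const double *Ji = Jm + (size_t)i * N;   // column i == row i (symmetric)
    for (int j = 0; j < N; ++j) loc += Ji[j] * s[j];
    const int Knew = K - s[i];
    const double dH = 2.0 * s[i] * loc + V[K] - V[Knew];
    if (dH <= 0.0 || runif01(rng) < std::exp(-dH / T)) {
      if (collect) {
        // close out the interval of the old values (attempts last+1 .. a-1)
        const double dt_g = static_cast<double>((a - 1) - last_g);
        if (dt_g > 0) {
          out->pk_sum[K] += dt_g;
          out->H_sum += H * dt_g; out->H2_sum += H * H * dt_g;
          const double M = 2.0 * K - N;
          out->M_sum += M * dt_g; out->M2_sum += M * M * dt_g;
        }
        last_g = a - 1;
        const double dt_i = static_cast<double>((a - 1) - last_i[i]);
        if (dt_i > 0) out->s_sum[i] += s[i] * dt_i;
        last_i[i] = a - 1;
      }
      s[i] = -s[i];
      H += dH;
      K = Knew;
    }
    if (collect && pair_stride > 0 && a % pair_stride == 0) {
      double *ps = out->pair_sum.data();
      for (int p = 0, ii = 0; ii < N; ++ii)
        for (int jj = ii + 1; jj < N; ++jj, ++p)
          ps[p] += s[ii] * s[jj];
      for (int tr = 0; tr < n_triples; ++tr)
        out->trip_sum[tr] += s[triples[tr]] * s[triples[tr + n_triples]] *
                             s[triples[tr + 2 * n_triples]];
      out->n_strided += 1.0;
    }
    if (raster != nullptr && a % raster_thin == 0) {
      for (int j = 0; j < N; ++j) (*raster)(*raster_row, j) = s[j];
      ++(*raster_row);
    }
  }
  if (collect) {
    const double dt_g = static_cast<double>(n_att - last_g);
    if (dt_g > 0) {
      out->pk_sum[K] += dt_g;
      out->H_sum += H * dt_g; out->H2_sum += H * H * dt_g;
      const double M = 2.0 * K - N;
      out->M_sum += M * dt_g; out->M2_sum += M * M * dt_g;
    }
    for (int i = 0; i < N; ++i) {
      const double dt_i = static_cast<double>(n_att - last_i[i]);
      if (dt_i > 0) out->s_sum[i] += s[i] * dt_i;
    }
  }
}

void init_spins(std::vector<int> &s, int N, int init_mode,
                const IntegerVector &init_state, std::mt19937_64 &rng) {
  s.resize(N);
  if (init_mode == 0) {
    std::uniform_real_distribution<double> runif01(0.0, 1.0);
    for (int i = 0; i < N; ++i) s[i] = runif01(rng) < 0.5 ? -1 : 1;
  } else if (init_mode == 1) {
    std::fill(s.begin(), s.end(), -1);
  } else {
    for (int i = 0; i < N; ++i) s[i] = init_state[i];
  }
}

} // namespace

// Multi-chain Metropolis sampling of P(s,T); returns per-chain averages.
// init_mode: 0 random, 1 all-silent (-1), 2 use init_state.
// [[Rcpp::export]]
List cpp_metropolis(NumericVector h, NumericMatrix J, NumericVector V,
                    double temperature, double n_attempts, double burn_in,
                    int n_chains, int init_mode, IntegerVector init_state,
                    int pair_stride, IntegerMatrix triples, int seed) {
  const int N = h.size();
  const int n_tr = triples.nrow();
  const int npair = N * (N - 1) / 2;

  NumericMatrix m_sig(n_chains, N), m_pk(n_chains, N + 1);
  NumericMatrix m_pair(pair_stride > 0 ? n_chains : 0, pair_stride > 0 ? npair : 0);
  NumericMatrix m_trip(n_tr > 0 ? n_chains : 0, n_tr);
  NumericVector mH(n_chains), mH2(n_chains), mM(n_chains), mM2(n_chains);

  for (int c = 0; c < n_chains; ++c) {
    std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL +
                        1000003ULL * (c + 1));
    std::vector<int> s;
    init_spins(s, N, init_mode, init_state, rng);
    ChainSums dummy;
    if (burn_in > 0)
      run_metropolis(h.begin(), J.begin(), V.begin(), N, temperature, burn_in,
                     s, rng, false, 0, nullptr, 0, &dummy, nullptr, 0, nullptr);
    ChainSums cs;
    run_metropolis(h.begin(), J.begin(), V.begin(), N, temperature, n_attempts,
                   s, rng, true, pair_stride, n_tr > 0 ? triples.begin() : nullptr,
                   n_tr, &cs, nullptr, 0, nullptr);
    const double n = cs.n_attempts;
    for (int i = 0; i < N; ++i) m_sig(c, i) = cs.s_sum[i] / n;
    for (int k = 0; k <= N; ++k) m_pk(c, k) = cs.pk_sum[k] / n;
    mH[c] = cs.H_sum / n; mH2[c] = cs.H2_sum / n;
    mM[c] = cs.M_sum / n; mM2[c] = cs.M2_sum / n;
    if (pair_stride > 0 && cs.n_strided > 0)
      for (int p = 0; p < npair; ++p) m_pair(c, p) = cs.pair_sum[p] / cs.n_strided;
    if (n_tr > 0 && cs.n_strided > 0)
      for (int tr = 0; tr < n_tr; ++tr) m_trip(c, tr) = cs.trip_sum[tr] / cs.n_strided;
  }

  return List::create(_["mean_sigma"] = m_sig, _["pk"] = m_pk,
                      _["pair"] = m_pair, _["triple"] = m_trip,
                      _["H"] = mH, _["H2"] = mH2, _["M"] = mM, _["M2"] = mM2);
}

// Draw a raster of Metropolis states thinned by `thin` attempts.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_raster(NumericVector h, NumericMatrix J, NumericVector V,
                                double temperature, int n_bins, int thin,
                                double burn_in, int init_mode,
                                IntegerVector init_state, int seed) {
  const int N = h.size();
  IntegerMatrix out(n_bins, N);
  if (n_bins == 0) return out;
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 77ULL);
  std::vector<int> s;
  init_spins(s, N, init_mode, init_state, rng);
  ChainSums dummy;
  if (burn_in > 0)
    run_metropolis(h.begin(), J.begin(), V.begin(), N, temperature, burn_in,
                   s, rng, false, 0, nullptr, 0, &dummy, nullptr, 0, nullptr);
  int row = 0;
  run_metropolis(h.begin(), J.begin(), V.begin(), N, temperature,
                 static_cast<double>(n_bins) * thin, s, rng, false, 0,
                 nullptr, 0, &dummy, &out, thin, &row);
  return out;
}

// Exact enumeration over all 2^N states (Gray-code order).
// Returns moments, P(K), energy/magnetization moments and log Z at the
// given temperature; optionally the full state probabilities and third
// moments <s_i s_j s_k> for the supplied triples.
// [[Rcpp::export]]
List cpp_enumerate(NumericVector h, NumericMatrix J, NumericVector V,
                   double temperature, bool return_probs,
                   IntegerMatrix triples) {
  const int N = h.size();
  if (N > 20) stop("exact enumeration is limited to N <= 20");
  const size_t nstate = (size_t)1 << N;
  const double T = temperature;
  const int n_tr = triples.nrow();

  std::vector<double> Hs(nstate);
  std::vector<int> s(N, -1);
  // all-down energy
  double H = 0.0;
  for (int i = 0; i < N; ++i) {
    H += h[i];
    for (int j = i + 1; j < N; ++j) H -= J(i, j);
  }
  H -= V[0];
  int K = 0;
  Hs[0] = H;
  double Hmin = H;
  std::vector<int> flip_bit(nstate);
  for (size_t m = 1; m < nstate; ++m) {
    int b = 0;
    while (!((m >> b) & 1)) ++b;
    flip_bit[m] = b;
    double loc = h[b];
    for (int j = 0; j < N; ++j) loc += J(b, j) * s[j];
    const int Knew = K - s[b];
    H += 2.0 * s[b] * loc + V[K] - V[Knew];
    s[b] = -s[b];
    K = Knew;
    Hs[m] = H;
    if (H < Hmin) Hmin = H;
  }

  double Zs = 0.0;
  std::vector<double> w(nstate);
  for (size_t m = 0; m < nstate; ++m) {
    w[m] = std::exp(-(Hs[m] - Hmin) / T);
    Zs += w[m];
  }
  const double logZ = std::log(Zs) - Hmin / T;

  NumericVector ms(N), pk(N + 1);
  const int npair = N * (N - 1) / 2;
  NumericVector mpair(npair), mtrip(n_tr);
  double EH = 0, EH2 = 0, EM = 0, EM2 = 0;
  NumericVector probs(return_probs ? nstate : 0);

  std::fill(s.begin(), s.end(), -1);
  K = 0;
  for (size_t m = 0; m < nstate; ++m) {
    if (m > 0) {
      const int b = flip_bit[m];
      K -= s[b];
      s[b] = -s[b];
    }
    const double p = w[m] / Zs;
    if (return_probs) probs[m] = p;
    pk[K] += p;
    const double M = 2.0 * K - N;
    EH += p * Hs[m]; EH2 += p * Hs[m] * Hs[m];
    EM += p * M; EM2 += p * M * M;
    for (int i = 0; i < N; ++i) ms[i] += p * s[i];
    for (int i = 0, q = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j, ++q) mpair[q] += p * s[i] * s[j];
    for (int tr = 0; tr < n_tr; ++tr)
      mtrip[tr] += p * s[triples(tr, 0)] * s[triples(tr, 1)] * s[triples(tr, 2)];
  }

  return List::create(_["logZ"] = logZ, _["mean_sigma"] = ms, _["pair"] = mpair,
                      _["pk"] = pk, _["H"] = EH, _["H2"] = EH2,
                      _["M"] = EM, _["M2"] = EM2,
                      _["triple"] = mtrip, _["probs"] = probs);
}

// Boltzmann-machine learning of the K-pairwise model.
// Gradient moments come from a persistent Metropolis chain re-equilibrated
// with `burn_in` attempts each iteration; learning rates theta(n) =
// theta0 * n^-alpha for h and V (switched to theta/P(K)_data for V after
// vk_switch_iter) and theta/2 for J.  V_0 and unfitted V_K stay pinned at 0.
// [[Rcpp::export]]
List cpp_bm_fit(NumericVector m_data, NumericVector pair_data,
                NumericVector pk_data, LogicalVector fit_vk,
                double theta0, double alpha, int vk_switch_iter,
                int max_iter, double mc_attempts, double burn_in,
                double tol_m, double tol_pk, int pair_stride,
                double param_abs_max, int seed, int trace_every) {
  const int N = m_data.size();
  const int npair = N * (N - 1) / 2;

  NumericVector hv(clone(m_data));              // h_i(1) = <s_i>_data
  NumericMatrix Jm(N, N);                       // zeros
  NumericVector Vv(N + 1);                      // zeros

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 13ULL);
  std::vector<int> s;
  IntegerVector dummy_init(0);
  init_spins(s, N, 0, dummy_init, rng);

  std::vector<double> tr_iter, tr_dm, tr_dpk, tr_dpair;
  bool converged = false, diverged = false;
  int n_done = 0;

  for (int n = 1; n <= max_iter; ++n) {
    ChainSums dummy;
    if (burn_in > 0)
      run_metropolis(hv.begin(), Jm.begin(), Vv.begin(), N, 1.0, burn_in,
                     s, rng, false, 0, nullptr, 0, &dummy, nullptr, 0, nullptr);
    ChainSums cs;
    run_metropolis(hv.begin(), Jm.begin(), Vv.begin(), N, 1.0, mc_attempts,
                   s, rng, true, pair_stride, nullptr, 0, &cs, nullptr, 0, nullptr);

    const double na = cs.n_attempts, nst = cs.n_strided;
    const double th = theta0 * std::pow(static_cast<double>(n), -alpha);
    double dm_max = 0, dpk_max = 0, dpair_max = 0;

    for (int i = 0; i < N; ++i) {
      const double d = cs.s_sum[i] / na - m_data[i];
      if (std::fabs(d) > dm_max) dm_max = std::fabs(d);
      hv[i] -= th * d;
    }
    for (int i = 0, p = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j, ++p) {
        const double d = cs.pair_sum[p] / nst - pair_data[p];
        if (std::fabs(d) > dpair_max) dpair_max = std::fabs(d);
        const double Jn = Jm(i, j) - 0.5 * th * d;
        Jm(i, j) = Jn; Jm(j, i) = Jn;
      }
    }
    for (int k = 1; k <= N; ++k) {                // K = 0 gauge-pinned
      if (!fit_vk[k]) continue;
      const double d = cs.pk_sum[k] / na - pk_data[k];
      const double rel = std::fabs(d) / pk_data[k];
      if (rel > dpk_max) dpk_max = rel;
      const double rate = (n <= vk_switch_iter) ? th : th / pk_data[k];
      Vv[k] -= rate * d;
    }
    n_done = n;

    if (trace_every > 0 && (n % trace_every == 0 || n == 1)) {
      tr_iter.push_back(n); tr_dm.push_back(dm_max);
      tr_dpk.push_back(dpk_max); tr_dpair.push_back(dpair_max);
    }
    for (int i = 0; i < N && !diverged; ++i)
      if (std::fabs(hv[i]) > param_abs_max) diverged = true;
    for (int k = 0; k <= N && !diverged; ++k)
      if (std::fabs(Vv[k]) > param_abs_max) diverged = true;
    if (!diverged)
      for (int i = 0; i < N * N && !diverged; ++i)
        if (std::fabs(Jm[i]) > param_abs_max) diverged = true;
    if (diverged) break;
    if (dm_max < tol_m && dpk_max < tol_pk) { converged = true; break; }
    if (n % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix trace(tr_iter.size(), 4);
  for (size_t r = 0; r < tr_iter.size(); ++r) {
    trace(r, 0) = tr_iter[r]; trace(r, 1) = tr_dm[r];
    trace(r, 2) = tr_dpk[r]; trace(r, 3) = tr_dpair[r];
  }
  return List::create(_["h"] = hv, _["J"] = Jm, _["V"] = Vv,
                      _["trace"] = trace, _["converged"] = converged,
                      _["diverged"] = diverged, _["n_iter"] = n_done);
}

// Three-point central-moment correlations T_ijk on a +/-1 raster
// (channels x bins), for the supplied 0-based triples.
// [[Rcpp::export]]
NumericVector cpp_three_point(IntegerMatrix sigma, IntegerMatrix triples) {
  const int N = sigma.nrow();
  const R_xlen_t Nb = sigma.ncol();
  const int n_tr = triples.nrow();
  std::vector<double> mu(N, 0.0);
  for (int i = 0; i < N; ++i) {
    double acc = 0;
    for (R_xlen_t k = 0; k < Nb; ++k) acc += sigma(i, k);
    mu[i] = acc / Nb;
  }
  NumericVector out(n_tr);
  for (int tr = 0; tr < n_tr; ++tr) {
    const int i = triples(tr, 0), j = triples(tr, 1), kk = triples(tr, 2);
    double acc = 0;
    for (R_xlen_t k = 0; k < Nb; ++k)
      acc += (sigma(i, k) - mu[i]) * (sigma(j, k) - mu[j]) *
             (sigma(kk, k) - mu[kk]);
    out[tr] = acc / Nb;
  }
  return out;
}
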