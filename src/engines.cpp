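// Simulation engines: single-site Wright-Fisher forward simulation and the
// single-locus Kingman coalescent under piecewise-exponential demography.
// Both use counter-style RNG substreams keyed by (seed, replicate index) so
// replicate r is reproducible independently of how many replicates are run.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Independent stream per (seed, stream); both fit in 2^31 on the R side.
static inline std::mt19937_64 make_rng(double seed, double stream) {
  std::uint64_t a = splitmix64(static_cast<std::uint64_t>(seed) + 0x8badf00dULL);
  std::uint64_t b = splitmix64(static_cast<std::uint64_t>(stream) + 0x5ca1ab1eULL);
  std::mt19937_64 rng(splitmix64(a ^ (b << 1)));
  rng.discard(8); // decorrelate nearby seeds
  return rng;
}

static inline long binom_draw(std::mt19937_64& rng, long n, double p) {
  if (p <= 0.0 || n <= 0) return 0L;
  if (p >= 1.0) return n;
  std::binomial_distribution<long> d(n, p);
  return d(rng);
}

// Forward Wright-Fisher recursion for one bi-allelic site.
//
// Per generation: (1) mutation pressure q' = q(1-v) + (1-q)u;
// (2) deterministic diploid viability selection
//     q'' = [q'^2 (1-s) + q'(1-q')(1-hs)] / wbar;
// (3) drift q <- Binomial(2N_t, q'') / 2N_t.
// Fixation is not absorbing (recurrent mutation re-seeds).
//
// n_burn generations at constant N_burn precede the epoch trajectory
// N_traj (diploid sizes ordered oldest -> present, one per generation).
// s_vec has length 1 (shared) or reps (per-replicate, used by ABC).
// [[Rcpp::export]]
List wf_sim_cpp(int n_burn, double N_burn, NumericVector N_traj,
                double u, double v, NumericVector s_vec, double h,
                int n_sample, bool hypergeom, double seed, double rep_offset,
                int reps, bool mock_ref) {
  const int T = N_traj.size();
  IntegerVector copies(reps);
  NumericVector qout(reps);
  LogicalVector refder(reps);
  IntegerVector wbar_zero(reps);

  for (int r = 0; r < reps; ++r) {
    const double s = (s_vec.size() == 1) ? s_vec[0] : s_vec[r];
    const double w11 = 1.0 - s, w01 = 1.0 - h * s;
    std::mt19937_64 rng = make_rng(seed, rep_offset + r);
    double q = 0.0;
    int nz = 0;
    for (int t = 0; t < n_burn + T; ++t) {
      const double N = (t < n_burn) ? N_burn : N_traj[t - n_burn];
      const long twoN = std::llround(2.0 * std::max(1.0, N));
      const double q1 = q * (1.0 - v) + (1.0 - q) * u;
      const double p1 = 1.0 - q1;
      const double wbar = q1 * q1 * w11 + 2.0 * q1 * p1 * w01 + p1 * p1;
      double q2;
      if (wbar <= 0.0) { // s = 1 and q' = 1: selection removes every carrier
        q2 = 0.0;
        ++nz;
      } else {
        q2 = (q1 * q1 * w11 + q1 * p1 * w01) / wbar;
      }
      q = static_cast<double>(binom_draw(rng, twoN, q2)) / static_cast<double>(twoN);
    }

    long c;
    if (hypergeom) {
      const double Nlast = (T > 0) ? N_traj[T - 1] : N_burn;
      const long twoN = std::llround(2.0 * std::max(1.0, Nlast));
      long K = std::llround(q * twoN), Nrem = twoN;
      std::uniform_real_distribution<double> U01(0.0, 1.0);
      c = 0;
      const int nd = (n_sample < twoN) ? n_sample : static_cast<int>(twoN);
      for (int i = 0; i < nd; ++i) {
        if (U01(rng) * Nrem < K) { ++c; --K; }
        --Nrem;
      }
    } else {
      c = binom_draw(rng, n_sample, q);
    }
    copies[r] = static_cast<int>(c);
    qout[r] = q;
    wbar_zero[r] = nz;
    if (mock_ref) {
      std::uniform_real_distribution<double> U01(0.0, 1.0);
      refder[r] = (U01(rng) < q);
    }
  }
  return List::create(_["copies"] = copies, _["pop_freq"] = qout,
                      _["ref_is_derived"] = refder, _["wbar_zero"] = wbar_zero);
}

// Total genealogy length of n chromosomes under piecewise-exponential
// demography, by time rescaling. ep rows are epochs ordered young -> old
// with columns (t_start, t_end, N_start, growth_rate); within an epoch the
// diploid size at tau generations before present is
// N(tau) = N_start * exp(growth_rate * (t_start - tau)), tau in [t_end, t_start).
// Beyond the oldest epoch the size is constant N_anc. Residual exponential
// deviates are carried across epoch boundaries; integrated rates are closed
// form, so there is no time discretization.
// [[Rcpp::export]]
NumericVector coal_len_cpp(double n, NumericMatrix ep, double N_anc,
                           int reps, double seed, double rep_offset) {
  const int nep = ep.nrow();
  NumericVector out(reps);
  for (int rep = 0; rep < reps; ++rep) {
    std::mt19937_64 rng = make_rng(seed, rep_offset + rep);
    std::exponential_distribution<double> Exp1(1.0);
    double k = n, tau = 0.0, len = 0.0;
    int ie = 0;
    while (k >= 2.0) {
      const double C = k * (k - 1.0) / 2.0;
      double E = Exp1(rng);
      bool placed = false;
      while (!placed) {
        if (ie >= nep) { // ancestral constant-size regime
          const double t = E * 2.0 * N_anc / C;
          len += k * t;
          tau += t;
          placed = true;
        } else {
          const double ts = ep(ie, 0), Ns = ep(ie, 2), g = ep(ie, 3);
          if (g == 0.0) {
            const double Lam = C * (ts - tau) / (2.0 * Ns);
            if (E <= Lam) {
              const double t = E * 2.0 * Ns / C;
              len += k * t;
              tau += t;
              placed = true;
            } else {
              E -= Lam;
              len += k * (ts - tau);
              tau = ts;
              ++ie;
            }
          } else {
            // integral of 1/(2N(tau)) from tau to ts
            const double ea = std::exp(-g * (ts - tau));
            const double Lam = C * (1.0 - ea) / (2.0 * Ns * g);
            if (E <= Lam) {
              const double x = ea + E * 2.0 * Ns * g / C;
              const double taun = ts + std::log(x) / g;
              len += k * (taun - tau);
              tau = taun;
              placed = true;
            } else {
              E -= Lam;
              len += k * (ts - tau);
              tau = ts;
              ++ie;
            }
          }
        }
      }
      k -= 1.0;
    }
    out[rep] = len;
  }
  return out;
}
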