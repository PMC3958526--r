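// Euler-Maruyama integrator for the four-species pluripotency network.
//
// Concentrations [OS], [N], [R] follow multiplicative-noise SDEs; [E] is
// integrated deterministically (no noise on the signalling pathway). All
// concentrations are clamped at zero after each full update. Each cell owns
// an independent RNG stream keyed by (master_seed, cell_id), so population
// output is bit-reproducible and independent of execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct CellRng {
  uint64_t s;
  bool has_spare;
  double spare;

  void seed(uint64_t master, uint64_t cell) {
    s = master * 0x9E3779B97F4A7C15ULL ^ (cell + 1) * 0xD1342543DE82EF95ULL;
    // warm up so nearby (master, cell) pairs decorrelate
    splitmix64(s); splitmix64(s); splitmix64(s);
    has_spare = false;
    spare = 0.0;
  }

  // uniform on (0, 1]
  double unif() {
    return (static_cast<double>(splitmix64(s) >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }

  // standard normal via Box-Muller with spare caching
  double norm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

inline double hill(double x, double k2, double n, double k) {
  if (x <= 0.0) return 0.0;
  if (n == 2.0) {
    double x2 = x * x;
    return x2 / (k2 + x2);
  }
  double xn = std::pow(x, n);
  return xn / (std::pow(k, n) + xn);
}

} // namespace

// par layout (1-based from R):
//  1 s12  2 s3  3 s4  4 s5  5 s6  6 s7  7 k  8 n  9 p
// 10 d_OS 11 d_N 12 d_R 13 d_E 14 i_OS 15 i_N 16 i_R
// 17 sigma_OS 18 sigma_N 19 sigma_R 20 Y 21 k_Y 22 h
// [[Rcpp::export]]
List sim_population_cpp(NumericVector par,
                        NumericMatrix init,
                        double duration,
                        double dt,
                        double master_seed,
                        NumericVector record_times,
                        LogicalVector record_species,
                        bool use_ramp,
                        NumericVector ramp_tmid,
                        double ramp_pmax,
                        double ramp_slope,
                        IntegerVector cell_ids) {
  const double s12 = par[0], s3 = par[1], s4 = par[2], s5 = par[3], s6 = par[4],
               s7 = par[5], k = par[6], n = par[7], p0 = par[8],
               dOS = par[9], dN = par[10], dR = par[11], dE = par[12],
               iOS = par[13], iN = par[14], iR = par[15],
               sgOS = par[16], sgN = par[17], sgR = par[18],
               Y = par[19], kY = par[20], h = par[21];
  const double k2 = k * k;
  const double kYh = (h == 2.0) ? kY * kY : std::pow(kY, h);
  const double sqdt = std::sqrt(dt);
  const int n_cells = init.nrow();
  const long nsteps = static_cast<long>(std::llround(duration / dt));

  // map record times onto the step grid
  const int n_rec = record_times.size();
  std::vector<long> rec_step(n_rec);
  for (int i = 0; i < n_rec; ++i)
    rec_step[i] = static_cast<long>(std::llround(record_times[i] / dt));

  const bool recOS = record_species[0], recN = record_species[1],
             recR = record_species[2], recE = record_species[3];
  NumericMatrix outOS(recOS ? n_rec : 0, recOS ? n_cells : 0);
  NumericMatrix outN(recN ? n_rec : 0, recN ? n_cells : 0);
  NumericMatrix outR(recR ? n_rec : 0, recR ? n_cells : 0);
  NumericMatrix outE(recE ? n_rec : 0, recE ? n_cells : 0);

  const uint64_t mseed = static_cast<uint64_t>(master_seed);
  CellRng rng;

  for (int j = 0; j < n_cells; ++j) {
    rng.seed(mseed, static_cast<uint64_t>(cell_ids[j]));
    double OS = init(j, 0), N = init(j, 1), R = init(j, 2), E = init(j, 3);
    const double tmid = use_ramp ? ramp_tmid[j] : 0.0;

    int rp = 0;
    if (rp < n_rec && rec_step[rp] == 0) {
      if (recOS) outOS(rp, j) = OS;
      if (recN) outN(rp, j) = N;
      if (recR) outR(rp, j) = R;
      if (recE) outE(rp, j) = E;
      ++rp;
    }

    for (long step = 1; step <= nsteps; ++step) {
      const double hOS = hill(OS, k2, n, k);
      const double hN = hill(N, k2, n, k);
      const double hE = hill(E, k2, n, k);

      double yin = 0.0;
      if (Y > 0.0) {
        const double Nh = (h == 2.0) ? N * N : (N > 0.0 ? std::pow(N, h) : 0.0);
        yin = Y * kYh / (kYh + Nh);
      }

      double p = p0;
      if (use_ramp) {
        const double t = (step - 1) * dt;
        p = ramp_pmax / (1.0 + std::exp(-ramp_slope * (t - tmid)));
      }
      const double gp = 1.0 / (1.0 + p * hE);

      const double fOS = s12 * hOS - dOS * (1.0 + iOS * yin) * OS;
      const double fN = (s3 * hOS + s4 * hN) * gp - dN * (1.0 + iN * yin) * N;
      const double fR = s5 * hOS + s6 * hN - dR * (1.0 + iR * yin) * R;
      const double fE = s7 * hOS - dE * E;

      OS += fOS * dt + sgOS * OS * sqdt * rng.norm();
      N += fN * dt + sgN * N * sqdt * rng.norm();
      R += fR * dt + sgR * R * sqdt * rng.norm();
      E += fE * dt;
      if (OS < 0.0) OS = 0.0;
      if (N < 0.0) N = 0.0;
      if (R < 0.0) R = 0.0;
      if (E < 0.0) E = 0.0;

      if (std::isnan(OS) || std::isnan(N) || std::isnan(R) || std::isnan(E))
        stop("non-finite concentration at step %ld (t = %.2f min) in cell %d",
             step, step * dt, cell_ids[j]);

      if (rp < n_rec && rec_step[rp] == step) {
        if (recOS) outOS(rp, j) = OS;
        if (recN) outN(rp, j) = N;
        if (recR) outR(rp, j) = R;
        if (recE) outE(rp, j) = E;
        ++rp;
      }
    }
  }

  return List::create(_["times"] = record_times,
                      _["OS"] = recOS ? SEXP(outOS) : R_NilValue,
                      _["N"] = recN ? SEXP(outN) : R_NilValue,
                      _["R"] = recR ? SEXP(outR) : R_NilValue,
                      _["E"] = recE ? SEXP(outE) : R_NilValue);
}
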