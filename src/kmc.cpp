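#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Freely-jointed-chain machinery and the Metropolis kinetic Monte Carlo
// core of the 1D DNA-zipper model. Forces in pN, lengths in nm, energies
// in pN nm unless stated otherwise.

struct ZipPhys {
  double k_spring;  // pN/nm, per spring (two springs act in series)
  double kT;        // pN nm
  double Lnt;       // ssDNA contour per nucleotide, nm
  double b;         // Kuhn length, nm
};

// Langevin function coth(x) - 1/x, stable near 0 and for large x
static double langevin(double x) {
  if (x < 1e-4) return x / 3.0 - x * x * x / 45.0;
  if (x > 30.0) return 1.0 - 1.0 / x;
  return 1.0 / std::tanh(x) - 1.0 / x;
}

static double dlangevin(double x) {
  if (x < 1e-4) return 1.0 / 3.0 - x * x / 15.0;
  if (x > 30.0) return 1.0 / (x * x);
  double s = std::sinh(x);
  return 1.0 / (x * x) - 1.0 / (s * s);
}

// log(sinh(x)/x), stable
static double log_sinhc(double x) {
  if (x < 1e-4) return x * x / 6.0 - x * x * x * x / 180.0;
  if (x > 30.0) return x - std::log(2.0 * x);
  return std::log(std::sinh(x) / x);
}

// total extension of the elastic chain: two springs in series plus
// 2*n_open FJC nucleotides
static double ext_total(double f, double n_open, const ZipPhys& P) {
  return 2.0 * f / P.k_spring +
         2.0 * n_open * P.Lnt * langevin(f * P.b / P.kT);
}

static double dext_df(double f, double n_open, const ZipPhys& P) {
  return 2.0 / P.k_spring +
         2.0 * n_open * P.Lnt * dlangevin(f * P.b / P.kT) * P.b / P.kT;
}

// solve ext_total(f) = z for f >= 0 (monotone; Newton with bisection
// safeguard, residual tolerance 1e-12 nm)
static double solve_force(double n_open, double z, const ZipPhys& P) {
  if (z <= 0.0) return 0.0;
  double lo = 0.0, hi = P.k_spring * z / 2.0 + 1.0;  // ext(hi) >= z
  double f;
  if (n_open <= 0.0) {
    f = P.k_spring * z / 2.0;  // springs only; exact
  } else {
    // Pade inverse-Langevin warm start in the FJC-dominated regime
    double y = z / (2.0 * n_open * P.Lnt);
    if (y > 0.97) y = 0.97;
    double xi = y * (3.0 - y * y) / (1.0 - y * y);
    f = xi * P.kT / P.b;
    if (f <= lo || f >= hi) f = 0.5 * hi;
  }
  for (int it = 0; it < 200; ++it) {
    double r = ext_total(f, n_open, P) - z;
    if (std::fabs(r) < 1e-12) return f;
    if (r > 0) hi = f; else lo = f;
    double step = r / dext_df(f, n_open, P);
    double fn = f - step;
    if (fn <= lo || fn >= hi) fn = 0.5 * (lo + hi);
    f = fn;
  }
  return f;
}

// elastic free energy at fixed tip height: spring term f^2/k plus the
// Helmholtz FJC free energy (Legendre transform of the Gibbs branch) of
// the 2*n_open released nucleotides
static double elastic_energy_f(double f, double n_open, const ZipPhys& P) {
  double xi = f * P.b / P.kT;
  double per_nt = f * P.Lnt * langevin(xi) -
                  (P.Lnt / P.b) * P.kT * log_sinhc(xi);
  return f * f / P.k_spring + 2.0 * n_open * per_nt;
}

// [[Rcpp::export]]
double solve_force_cpp(double n_open, double z, double k_spring, double kT,
                       double contour_per_nt, double kuhn_length) {
  ZipPhys P{k_spring, kT, contour_per_nt, kuhn_length};
  return solve_force(n_open, z, P);
}

// [[Rcpp::export]]
NumericVector solve_force_vec_cpp(NumericVector n_open, NumericVector z,
                                  double k_spring, double kT,
                                  double contour_per_nt, double kuhn_length) {
  ZipPhys P{k_spring, kT, contour_per_nt, kuhn_length};
  int n = n_open.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = solve_force(n_open[i], z[i], P);
  return out;
}

// [[Rcpp::export]]
double elastic_energy_cpp(double n_open, double z, double k_spring, double kT,
                          double contour_per_nt, double kuhn_length) {
  ZipPhys P{k_spring, kT, contour_per_nt, kuhn_length};
  double f = solve_force(n_open, z, P);
  return elastic_energy_f(f, n_open, P);
}

// Metropolis KMC over the fork coordinate n_open.
// phases: columns t_start, t_end, z0, vz; z(t) = z0 + vz*(t - t_start).
// cost_kT[i] = opening cost of pair i+1 in units of kT.
// Returns sampled frames (t, z, n_open, force) and the termination cause.
// [[Rcpp::export]]
List kmc_core(NumericVector cost_kT, double k_spring, double kT,
              double contour_per_nt, double kuhn_length,
              double attempt_rate, NumericMatrix phases,
              bool release_after_pull, double release_time,
              double rupture_pN, double tension_eps_pN,
              int sample_stride, bool terminate_on_separation) {
  ZipPhys P{k_spring, kT, contour_per_nt, kuhn_length};
  int n_bp = cost_kT.size();
  double t_end = phases(phases.nrow() - 1, 1);
  long n_attempts = (long)std::ceil(t_end * attempt_rate);
  double dt = 1.0 / attempt_rate;

  std::vector<double> out_t, out_z, out_f;
  std::vector<int> out_n;
  out_t.reserve(n_attempts / sample_stride + 2);
  out_z.reserve(n_attempts / sample_stride + 2);
  out_f.reserve(n_attempts / sample_stride + 2);
  out_n.reserve(n_attempts / sample_stride + 2);

  int n_open = 0;
  int phase = 0;
  std::string termination = "completed";
  double f_cur = 0.0;

  RNGScope scope;
  for (long i = 0; i < n_attempts; ++i) {
    double t = (i + 1) * dt;
    while (phase < phases.nrow() - 1 && t >= phases(phase, 1)) ++phase;
    double z = phases(phase, 2) + phases(phase, 3) * (t - phases(phase, 0));
    if (z < 0) z = 0;
    bool released = release_after_pull && t >= release_time;

    double A_cur, A_new;
    if (released) {
      f_cur = 0.0;
      A_cur = 0.0;
    } else if (n_open == n_bp) {
      f_cur = 0.0;
      A_cur = 0.0;
    } else {
      f_cur = solve_force(n_open, z, P);
      A_cur = elastic_energy_f(f_cur, n_open, P);
    }
    if (f_cur > rupture_pN) { termination = "ruptured"; break; }

    int dn = (unif_rand() < 0.5) ? 1 : -1;
    int n_new = n_open + dn;
    if (n_new >= 0 && n_new <= n_bp) {  // reflecting boundaries
      if (released || n_new == n_bp) {
        A_new = 0.0;
      } else {
        A_new = elastic_energy_f(solve_force(n_new, z, P), n_new, P);
      }
      double dE = (dn > 0 ? cost_kT[n_open] : -cost_kT[n_new]) +
                  (A_new - A_cur) / P.kT;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        bool was_tense = f_cur > tension_eps_pN;
        n_open = n_new;
        if (n_open == n_bp && !released && was_tense &&
            terminate_on_separation) {
          termination = "separated";
          out_t.push_back(t); out_z.push_back(z);
          out_n.push_back(n_open); out_f.push_back(0.0);
          break;
        }
      }
    }

    if ((i + 1) % sample_stride == 0 || i == n_attempts - 1) {
      double f_s = (released || n_open == n_bp)
                       ? 0.0 : solve_force(n_open, z, P);
      out_t.push_back(t);
      out_z.push_back(z);
      out_n.push_back(n_open);
      out_f.push_back(f_s);
    }
  }

  return List::create(
    _["t"] = wrap(out_t), _["z_tip"] = wrap(out_z),
    _["n_open"] = wrap(out_n), _["force"] = wrap(out_f),
    _["termination"] = termination);
}
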