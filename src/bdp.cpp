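#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Density-dependent birth / density-independent death propensities of the
// stochastic logistic model:
//   B(n) = theta1 * n * (1 - theta2 * n / N)   (clamped at 0)
//   D(n) = theta3 * n
static inline double birth_rate(double theta1, double theta2, double N,
                                double n) {
  double b = theta1 * n * (1.0 - theta2 * n / N);
  return b > 0.0 ? b : 0.0;
}

// Exact (Gillespie) sample path of the birth-death process, recording every
// event up to `horizon`. Uses R's RNG so seeding via set.seed() applies.
// [[Rcpp::export]]
List gillespie_cpp(double theta1, double theta2, double theta3, double N,
                   int n0, double horizon) {
  std::vector<double> times;
  std::vector<int> sizes;
  times.reserve(4096);
  sizes.reserve(4096);
  double t = 0.0;
  long n = n0;
  for (;;) {
    double b = birth_rate(theta1, theta2, N, (double)n);
    double d = theta3 * (double)n;
    double tot = b + d;
    if (n == 0 || tot <= 0.0) break;  // absorbed or frozen state
    t += R::exp_rand() / tot;
    if (t > horizon) break;
    if (R::unif_rand() * tot < b) ++n; else --n;
    times.push_back(t);
    sizes.push_back((int)n);
  }
  return List::create(_["times"] = times, _["sizes"] = sizes);
}

// Fused simulate-and-sample: returns the state of one Gillespie path at the
// (sorted, increasing) times `at`, without materialising the full event
// history. State at time s is the state after the last event <= s
// (right-continuous CTMC convention).
// [[Rcpp::export]]
IntegerVector gillespie_states_cpp(double theta1, double theta2, double theta3,
                                   double N, int n0, NumericVector at) {
  int m = at.size();
  IntegerVector out(m);
  double t = 0.0;
  long n = n0;
  int k = 0;
  while (k < m) {
    double b = birth_rate(theta1, theta2, N, (double)n);
    double d = theta3 * (double)n;
    double tot = b + d;
    if (tot <= 0.0) {                // absorbed/frozen: state never changes
      for (; k < m; ++k) out[k] = (int)n;
      break;
    }
    double tnext = t + R::exp_rand() / tot;
    for (; k < m && at[k] < tnext; ++k) out[k] = (int)n;
    if (k >= m) break;
    t = tnext;
    if (R::unif_rand() * tot < b) ++n; else --n;
  }
  return out;
}

// Mean/variance moment ODEs of the birth-death process (diffusion
// approximation):
//   dm/dt = B(m) - D(m)
//   dV/dt = 2 V (B'(m) - D'(m)) + B(m) + D(m)
// Fixed-step classical RK4; `times` sorted increasing, >= 0. Returns a
// length(times) x 2 matrix with columns (mean, variance).
// [[Rcpp::export]]
NumericMatrix moment_path_cpp(double theta1, double theta2, double theta3,
                              double N, double n0, NumericVector times,
                              double dt) {
  int K = times.size();
  NumericMatrix out(K, 2);
  double m = n0, V = 0.0, t = 0.0;

  struct Deriv {
    double th1, th2, th3, N;
    inline void operator()(double m, double V, double &dm, double &dV) const {
      double B = th1 * m * (1.0 - th2 * m / N);
      double Bp = th1 * (1.0 - 2.0 * th2 * m / N);
      if (B < 0.0) { B = 0.0; Bp = 0.0; }
      double D = th3 * m;
      dm = B - D;
      dV = 2.0 * V * (Bp - th3) + B + D;
    }
  } f{theta1, theta2, theta3, N};

  for (int k = 0; k < K; ++k) {
    double target = times[k];
    while (t < target - 1e-12) {
      double h = std::min(dt, target - t);
      double k1m, k1v, k2m, k2v, k3m, k3v, k4m, k4v;
      f(m, V, k1m, k1v);
      f(m + 0.5 * h * k1m, V + 0.5 * h * k1v, k2m, k2v);
      f(m + 0.5 * h * k2m, V + 0.5 * h * k2v, k3m, k3v);
      f(m + h * k3m, V + h * k3v, k4m, k4v);
      m += h / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
      V += h / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      if (m < 0.0) m = 0.0;
      if (V < 0.0) V = 0.0;
      t += h;
    }
    out(k, 0) = m;
    out(k, 1) = V;
  }
  return out;
}
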