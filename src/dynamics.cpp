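#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// x^e with the convention 0^0 = 1, so that a beta of 0 lets an extinct
// language regain speakers and alpha == beta removes the aversion term.
static inline double pow0(double base, double e) {
  if (e == 0.0) return 1.0;
  return std::pow(base, e);
}

// Net flow for each language: gain_i = sum_{j != i} x_j * P(j -> i),
// loss_i = x_i * sum_{j != i} P(i -> j), with
// P(j -> i) = s_i * x_i^beta * (1 - x_j)^(alpha - beta).
static void flow(const std::vector<double>& x, const std::vector<double>& s,
                 double alpha, double beta, std::vector<double>& dx) {
  const int n = static_cast<int>(x.size());
  std::vector<double> att(n), esc(n);
  for (int i = 0; i < n; ++i) {
    att[i] = s[i] * pow0(x[i], beta);          // pull toward language i
    esc[i] = pow0(1.0 - x[i], alpha - beta);   // ease of leaving for i's rivals
  }
  for (int i = 0; i < n; ++i) {
    double gain = 0.0, out_rate = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      gain += x[j] * att[i] * esc[j];
      out_rate += att[j] * esc[i];
    }
    dx[i] = gain - x[i] * out_rate;
  }
}

// One explicit Euler step followed by clipping to [0,1] and renormalisation,
// which keeps the state on the simplex against floating-point drift.
static void euler_step(std::vector<double>& x, const std::vector<double>& s,
                       double alpha, double beta, double dt,
                       std::vector<double>& dx) {
  const int n = static_cast<int>(x.size());
  flow(x, s, alpha, beta, dx);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = x[i] + dt * dx[i];
    if (v < 0.0) v = 0.0;
    if (v > 1.0) v = 1.0;
    x[i] = v;
    tot += v;
  }
  for (int i = 0; i < n; ++i) x[i] /= tot;
}

// [[Rcpp::export]]
NumericVector cpp_flow(NumericVector x, NumericVector s, double alpha,
                       double beta) {
  std::vector<double> xv(x.begin(), x.end()), sv(s.begin(), s.end());
  std::vector<double> dx(xv.size());
  flow(xv, sv, alpha, beta, dx);
  return NumericVector(dx.begin(), dx.end());
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector s, double alpha, double beta,
                           NumericVector x0, int n_steps, double dt) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), sv(s.begin(), s.end()), dx(n);
  NumericMatrix out(n_steps + 1, n);
  for (int i = 0; i < n; ++i) out(0, i) = x[i];
  for (int k = 1; k <= n_steps; ++k) {
    euler_step(x, sv, alpha, beta, dt, dx);
    for (int i = 0; i < n; ++i) out(k, i) = x[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_find_steady(NumericVector s, double alpha, double beta,
                     NumericVector x0, double tol, double max_time,
                     double dt) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), sv(s.begin(), s.end()), dx(n);
  std::vector<double> prev(n);
  double t = 0.0;
  bool converged = false;
  while (t < max_time - 1e-12) {
    prev = x;
    euler_step(x, sv, alpha, beta, dt, dx);
    t += dt;
    double maxdiff = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(x[i] - prev[i]);
      if (d > maxdiff) maxdiff = d;
    }
    if (maxdiff < tol) {
      converged = true;
      break;
    }
  }
  if (!converged) t = max_time;
  return List::create(_["equilibrium"] = NumericVector(x.begin(), x.end()),
                      _["tau"] = t, _["converged"] = converged);
}

// Sum over languages and census time points of squared differences between
// the observed fractions and a yearly Euler simulation sampled at the
// census offsets (offsets[k] = census year k minus first census year).
// [[Rcpp::export]]
double cpp_distance(NumericVector s, double alpha, double beta,
                    NumericVector x0, IntegerVector offsets,
                    NumericMatrix obs) {
  const int n = x0.size();
  const int m = offsets.size();
  std::vector<double> x(x0.begin(), x0.end()), sv(s.begin(), s.end()), dx(n);
  int last = 0;
  for (int k = 0; k < m; ++k)
    if (offsets[k] > last) last = offsets[k];
  double acc = 0.0;
  int next = 0;
  for (int step = 0; step <= last; ++step) {
    if (step > 0) euler_step(x, sv, alpha, beta, 1.0, dx);
    while (next < m && offsets[next] == step) {
      for (int i = 0; i < n; ++i) {
        double d = x[i] - obs(next, i);
        acc += d * d;
      }
      ++next;
    }
  }
  return acc;
}
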