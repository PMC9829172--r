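#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Within-cycle consumer-resource dynamics in log space.
//
// State w = (log N_1..S, log c_1..R).  With Monod co-utilization
//   dN_i/dt  =  sum_r x_ir g_ir c_r/(c_r+K_ir) N_i
//   dc_r/dt  = -sum_i x_ir g_ir c_r/(c_r+K_ir) N_i / yield_i
// the log-space right-hand side is
//   dlogN_i/dt =  sum_r x_ir g_ir c_r/(c_r+K_ir)
//   dlogc_r/dt = -sum_i x_ir g_ir N_i/((c_r+K_ir) yield_i)
// which stays finite as c_r -> 0 (log c then decays linearly, so the
// depletion phase is not stiff for an explicit solver and the leftover
// concentration keeps full relative precision however small it gets).

struct Model {
  int S, R;
  const double *g, *K, *x;   // S x R, column-major
  const double *invy;        // length S
  std::vector<double> N, c;  // scratch

  Model(int S_, int R_, const double *g_, const double *K_, const double *x_,
        const double *invy_)
      : S(S_), R(R_), g(g_), K(K_), x(x_), invy(invy_), N(S_), c(R_) {}

  void rhs(const double *w, double *dw) {
    for (int i = 0; i < S; ++i) N[i] = std::exp(w[i]);
    for (int r = 0; r < R; ++r) c[r] = std::exp(w[S + r]);
    for (int i = 0; i < S; ++i) dw[i] = 0.0;
    for (int r = 0; r < R; ++r) {
      const double cr = c[r];
      double duc = 0.0;
      const double *gc = g + (size_t)r * S;
      const double *Kc = K + (size_t)r * S;
      const double *xc = x + (size_t)r * S;
      for (int i = 0; i < S; ++i) {
        const double m = xc[i] * gc[i] / (cr + Kc[i]);
        dw[i] += m * cr;
        duc += m * N[i] * invy[i];
      }
      dw[S + r] = -duc;
    }
  }
};

// Dormand-Prince 5(4) with standard step control.  Magnitudes entering the
// relative error scale are capped at 100 so that very negative log c
// (deep depletion) is still resolved to ~rtol in log units.
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// Integrate from t=0 to t=T in place; returns steps taken, or -1 on failure.
static long integrate(Model &M, std::vector<double> &w, double T, double rtol,
                      double atol) {
  const int n = M.S + M.R;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      wtmp(n), w5(n);
  double t = 0.0, h = std::min(0.05, T);
  const double hmin = T * 1e-14;
  long steps = 0;
  bool have_k1 = false;
  while (t < T) {
    if (h > T - t) h = T - t;
    if (!have_k1) M.rhs(w.data(), k1.data());
    for (int i = 0; i < n; ++i) wtmp[i] = w[i] + h * a21 * k1[i];
    M.rhs(wtmp.data(), k2.data());
    for (int i = 0; i < n; ++i)
      wtmp[i] = w[i] + h * (a31 * k1[i] + a32 * k2[i]);
    M.rhs(wtmp.data(), k3.data());
    for (int i = 0; i < n; ++i)
      wtmp[i] = w[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    M.rhs(wtmp.data(), k4.data());
    for (int i = 0; i < n; ++i)
      wtmp[i] =
          w[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    M.rhs(wtmp.data(), k5.data());
    for (int i = 0; i < n; ++i)
      wtmp[i] = w[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    M.rhs(wtmp.data(), k6.data());
    for (int i = 0; i < n; ++i)
      w5[i] = w[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    M.rhs(w5.data(), k7.data());
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      const double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double mag = std::min(std::max(std::fabs(w[i]), std::fabs(w5[i])),
                                  100.0);
      const double sc = atol + rtol * mag;
      const double q = err / sc;
      errnorm += q * q;
    }
    errnorm = std::sqrt(errnorm / n);
    if (errnorm <= 1.0) {
      t += h;
      w.swap(w5);
      k1.swap(k7);  // FSAL
      have_k1 = true;
    }
    // on rejection k1 is still the derivative at the current point
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < hmin) return -1;
    if (++steps > 50000000L) return -1;
  }
  return steps;
}

// [[Rcpp::export(name = ".cycle_cpp")]]
List cycle_cpp(NumericVector logN0, NumericVector logc0, NumericMatrix g,
               NumericMatrix K, NumericMatrix x, NumericVector yield,
               double T, double rtol, double atol) {
  const int S = logN0.size(), R = logc0.size();
  if (g.nrow() != S || g.ncol() != R || K.nrow() != S || K.ncol() != R ||
      x.nrow() != S || x.ncol() != R || yield.size() != S)
    stop("parameter dimensions do not match state dimensions");
  std::vector<double> invy(S);
  for (int i = 0; i < S; ++i) invy[i] = 1.0 / yield[i];
  Model M(S, R, g.begin(), K.begin(), x.begin(), invy.data());
  std::vector<double> w(S + R);
  for (int i = 0; i < S; ++i) w[i] = logN0[i];
  for (int r = 0; r < R; ++r) w[S + r] = logc0[r];
  long steps = integrate(M, w, T, rtol, atol);
  if (steps < 0) stop("cycle integration failed (step size underflow)");
  NumericVector logN(S), logc(R);
  for (int i = 0; i < S; ++i) logN[i] = w[i];
  for (int r = 0; r < R; ++r) logc[r] = w[S + r];
  return List::create(_["logN"] = logN, _["logc"] = logc,
                      _["steps"] = (double)steps);
}

// Serial growth-dilution loop: integrate a cycle, dilute abundances by D,
// refresh every resource to c0 (leftovers discarded), prune strains below the
// relative extinction threshold, and stop when start-of-cycle log abundances
// of the remaining strains change by less than tol.
// [[Rcpp::export(name = ".assemble_cpp")]]
List assemble_cpp(NumericVector logN0, NumericMatrix g, NumericMatrix K,
                  NumericMatrix x, NumericVector yield, NumericVector c0,
                  double D, double T, int max_cycles, double tol,
                  double extinction, double rtol, double atol) {
  const int S0 = logN0.size(), R = c0.size();
  if (g.nrow() != S0 || g.ncol() != R) stop("parameter dimensions mismatch");
  const double logD = std::log(D);
  std::vector<double> logc0(R);
  for (int r = 0; r < R; ++r) logc0[r] = std::log(c0[r]);

  std::vector<int> alive(S0);
  for (int i = 0; i < S0; ++i) alive[i] = i;
  std::vector<double> cur(logN0.begin(), logN0.end());  // start-of-cycle
  std::vector<double> invy_all(S0);
  for (int i = 0; i < S0; ++i) invy_all[i] = 1.0 / yield[i];

  bool converged = false;
  int cycles = 0;
  std::vector<double> prev, fold(S0, NA_REAL), delta(S0, NA_REAL);
  std::vector<double> end_logc(R);

  while (cycles < max_cycles && !alive.empty()) {
    const int S = (int)alive.size();
    // compact parameter copies for the alive set
    std::vector<double> gs((size_t)S * R), Ks((size_t)S * R),
        xs((size_t)S * R), invy(S);
    for (int r = 0; r < R; ++r)
      for (int i = 0; i < S; ++i) {
        gs[(size_t)r * S + i] = g(alive[i], r);
        Ks[(size_t)r * S + i] = K(alive[i], r);
        xs[(size_t)r * S + i] = x(alive[i], r);
      }
    for (int i = 0; i < S; ++i) invy[i] = invy_all[alive[i]];

    std::vector<double> w(S + R);
    for (int i = 0; i < S; ++i) w[i] = cur[i];
    for (int r = 0; r < R; ++r) w[S + r] = logc0[r];
    Model M(S, R, gs.data(), Ks.data(), xs.data(), invy.data());
    if (integrate(M, w, T, rtol, atol) < 0)
      stop("cycle integration failed (step size underflow) at cycle %d",
           cycles + 1);
    ++cycles;

    for (int r = 0; r < R; ++r) end_logc[r] = w[S + r];
    for (int i = 0; i < S; ++i) fold[alive[i]] = w[i] - cur[i];

    // dilute
    std::vector<double> nxt(S);
    for (int i = 0; i < S; ++i) nxt[i] = w[i] - logD;

    // extinction pruning (relative to current total, plus absolute floor)
    double total = 0.0;
    for (int i = 0; i < S; ++i) total += std::exp(nxt[i]);
    const double cut = std::log(extinction * total);
    std::vector<int> keep;
    keep.reserve(S);
    for (int i = 0; i < S; ++i)
      if (nxt[i] > cut && nxt[i] > -690.0) keep.push_back(i);

    if ((int)keep.size() != S) {
      // strain set changed: compact and restart the convergence comparison
      std::vector<int> alive2;
      std::vector<double> cur2;
      for (int j : keep) {
        alive2.push_back(alive[j]);
        cur2.push_back(nxt[j]);
        delta[alive[j]] = NA_REAL;
      }
      alive.swap(alive2);
      cur.swap(cur2);
      prev.clear();
    } else {
      if ((int)prev.size() == S) {
        double dmax = 0.0;
        for (int i = 0; i < S; ++i) {
          const double d = nxt[i] - prev[i];
          delta[alive[i]] = d;
          if (std::fabs(d) > dmax) dmax = std::fabs(d);
        }
        if (dmax < tol) converged = true;
      }
      prev.assign(nxt.begin(), nxt.end());
      cur.assign(nxt.begin(), nxt.end());
      if (converged) break;
    }
  }

  const int S = (int)alive.size();
  IntegerVector alive_idx(S);
  NumericVector start_logN(S), foldv(S), deltav(S), endN(S), endc(R);
  for (int i = 0; i < S; ++i) {
    alive_idx[i] = alive[i] + 1;
    start_logN[i] = cur[i];
    foldv[i] = fold[alive[i]];
    deltav[i] = delta[alive[i]];
  }
  // survivors' end-of-cycle abundances: start of next cycle times D
  for (int i = 0; i < S; ++i) endN[i] = cur[i] + logD;
  for (int r = 0; r < R; ++r) endc[r] = end_logc[r];
  return List::create(_["alive"] = alive_idx, _["start_logN"] = start_logN,
                      _["end_logN"] = endN, _["end_logc"] = endc,
                      _["log_fold"] = foldv, _["delta_log"] = deltav,
                      _["cycles"] = cycles, _["converged"] = converged);
}
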