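// Core numerics for the time-sliced BiSSE likelihood.
//
// State vector y = (E0, E1, D0, D1), integrated in units of age (Ma before
// present), i.e. from the younger end of a branch towards the older end.
// Rates are piecewise constant in age: epoch 0 is the most recent interval
// [0, b1), epoch j is [b_j, b_{j+1}).  An age exactly at a breakpoint
// belongs to the older epoch.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void bisse_rhs(const double *y, double *dy, const double *r) {
  // r = {l0, l1, m0, m1, q01, q10}
  const double l0 = r[0], l1 = r[1], m0 = r[2], m1 = r[3], q01 = r[4],
               q10 = r[5];
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = m0 - (l0 + m0 + q01) * E0 + q01 * E1 + l0 * E0 * E0;
  dy[1] = m1 - (l1 + m1 + q10) * E1 + q10 * E0 + l1 * E1 * E1;
  dy[2] = -(l0 + m0 + q01) * D0 + q01 * D1 + 2.0 * l0 * E0 * D0;
  dy[3] = -(l1 + m1 + q10) * D1 + q10 * D0 + 2.0 * l1 * E1 * D1;
}

// Dormand-Prince 5(4) adaptive step over one constant-rate interval.
static void integrate_const(double *y, double t0, double t1, const double *r,
                            double rtol, double atol) {
  const double span = t1 - t0;
  if (span <= 0.0) return;
  // Butcher tableau (Dormand & Prince 1980)
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

  double t = t0;
  double h = std::min(span, 0.1);
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], yt[4], ynew[4];
  bisse_rhs(y, k1, r);
  int n_reject = 0, n_step = 0;
  const int max_step = 1000000;
  while (t < t1 && n_step < max_step) {
    ++n_step;
    if (t + h > t1) h = t1 - t;
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * a21 * k1[i];
    bisse_rhs(yt, k2, r);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    bisse_rhs(yt, k3, r);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    bisse_rhs(yt, k4, r);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    bisse_rhs(yt, k5, r);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    bisse_rhs(yt, k6, r);
    for (int i = 0; i < 4; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    bisse_rhs(ynew, k7, r);
    double err = 0.0;
    for (int i = 0; i < 4; ++i) {
      double sk = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      err += (e / sk) * (e / sk);
    }
    err = std::sqrt(err / 4.0);
    if (err <= 1.0 || h <= 1e-14) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = ynew[i];
      for (int i = 0; i < 4; ++i) k1[i] = k7[i];  // FSAL
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      if (n_reject > 0 && fac > 1.0) fac = 1.0;
      h *= fac;
      n_reject = 0;
    } else {
      double fac = std::max(0.2, 0.9 * std::pow(err, -0.2));
      h *= fac;
      ++n_reject;
    }
    // keep E inside [0,1] against round-off
    for (int i = 0; i < 2; ++i) {
      if (y[i] < 0.0) y[i] = 0.0;
      if (y[i] > 1.0) y[i] = 1.0;
    }
  }
  if (n_step >= max_step) stop("ODE integrator failed to converge");
  (void)c2; (void)c3; (void)c4; (void)c5;
}

// Integrate y over [a0, a1], switching rate epochs at breakpoints.
static void integrate_slices(double *y, double a0, double a1,
                             const NumericMatrix &rates,
                             const NumericVector &breaks, double rtol,
                             double atol) {
  if (a1 <= a0) return;
  const int nb = breaks.size();
  double lo = a0;
  for (int j = 0; j <= nb; ++j) {
    double hi = (j < nb) ? breaks[j] : a1;
    if (hi > a1) hi = a1;
    if (hi > lo) {
      double r[6];
      for (int k = 0; k < 6; ++k) r[k] = rates(j, k);
      integrate_const(y, lo, hi, r, rtol, atol);
      lo = hi;
    }
    if (lo >= a1) break;
  }
}

static inline int epoch_of(double age, const NumericVector &breaks) {
  int e = 0;
  for (int j = 0; j < breaks.size(); ++j)
    if (breaks[j] <= age) ++e;
  return e;
}

// [[Rcpp::export(name = ".bisse_ode_cpp")]]
NumericVector bisse_ode_cpp(NumericVector y0, double a0, double a1,
                            NumericMatrix rates, NumericVector breaks,
                            double rtol, double atol) {
  if (y0.size() != 4) stop("y0 must have length 4");
  double y[4];
  for (int i = 0; i < 4; ++i) y[i] = y0[i];
  integrate_slices(y, a0, a1, rates, breaks, rtol, atol);
  return NumericVector::create(y[0], y[1], y[2], y[3]);
}

// Full post-order pruning likelihood.
//
// edge: 2-column matrix (parent, child) in post-order, 1-based node ids as
//   in an ape phylo (tips 1..ntip, root ntip+1).  node_age: age of every
//   node.  tip_state: 0/1 per tip.  root_mode: 0 = FitzJohn state weights,
//   1 = equal, 2 = supplied prior.
// [[Rcpp::export(name = ".bisse_loglik_cpp")]]
List bisse_loglik_cpp(IntegerMatrix edge, NumericVector node_age,
                      IntegerVector tip_state, int ntip, NumericMatrix rates,
                      NumericVector breaks, double f0, double f1,
                      int root_mode, NumericVector root_prior, bool condition,
                      double rtol, double atol) {
  const int nnode = node_age.size();
  const int nedge = edge.nrow();
  std::vector<double> D0(nnode, -1.0), D1(nnode, -1.0);
  std::vector<double> E0v(nnode, 0.0), E1v(nnode, 0.0);
  std::vector<int> nseen(nnode, 0);
  double logcomp = 0.0;

  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1;
    const int ch = edge(e, 1) - 1;
    double y[4];
    if (ch < ntip) {
      const int s = tip_state[ch];
      y[0] = 1.0 - f0;
      y[1] = 1.0 - f1;
      y[2] = (s == 0) ? f0 : 0.0;
      y[3] = (s == 1) ? f1 : 0.0;
    } else {
      if (nseen[ch] != 2) stop("post-order violated: child not resolved");
      y[0] = E0v[ch];
      y[1] = E1v[ch];
      y[2] = D0[ch];
      y[3] = D1[ch];
    }
    const double a0 = node_age[ch], a1 = node_age[par];
    if (a1 - a0 > 1e-12)
      integrate_slices(y, a0, a1, rates, breaks, rtol, atol);
    if (!R_finite(y[2]) || !R_finite(y[3]) || (y[2] < 0) || (y[3] < 0))
      stop("non-finite branch likelihood");
    if (nseen[par] == 0) {
      E0v[par] = y[0];
      E1v[par] = y[1];
      D0[par] = y[2];
      D1[par] = y[3];
      nseen[par] = 1;
    } else if (nseen[par] == 1) {
      // average E from the two descendant passes (they agree analytically)
      E0v[par] = 0.5 * (E0v[par] + y[0]);
      E1v[par] = 0.5 * (E1v[par] + y[1]);
      const int ep = epoch_of(node_age[par], breaks);
      D0[par] = rates(ep, 0) * D0[par] * y[2];
      D1[par] = rates(ep, 1) * D1[par] * y[3];
      nseen[par] = 2;
      double mx = std::max(D0[par], D1[par]);
      if (mx > 0.0) {
        D0[par] /= mx;
        D1[par] /= mx;
        logcomp += std::log(mx);
      } else {
        stop("likelihood underflow: both partials zero at an internal node");
      }
    } else {
      stop("polytomy encountered; the pruning likelihood requires a binary tree");
    }
  }

  const int root = edge(nedge - 1, 0) - 1;
  if (nseen[root] != 2) stop("root not resolved after post-order sweep");
  const double d0 = D0[root], d1 = D1[root];
  const double e0r = E0v[root], e1r = E1v[root];
  const int ep = epoch_of(node_age[root], breaks);
  double w0, w1;
  if (root_mode == 0) {
    const double s = d0 + d1;
    w0 = d0 / s;
    w1 = d1 / s;
  } else if (root_mode == 1) {
    w0 = w1 = 0.5;
  } else {
    w0 = root_prior[0];
    w1 = root_prior[1];
  }
  double c0 = d0, c1 = d1;
  if (condition) {
    c0 /= rates(ep, 0) * (1.0 - e0r) * (1.0 - e0r);
    c1 /= rates(ep, 1) * (1.0 - e1r) * (1.0 - e1r);
  }
  const double L = w0 * c0 + w1 * c1;
  double ll = std::log(L) + logcomp;
  return List::create(_["loglik"] = ll,
                      _["root_D"] = NumericVector::create(d0, d1),
                      _["root_E"] = NumericVector::create(e0r, e1r),
                      _["logcomp"] = logcomp);
}
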