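// Gibbs sampler for the Barry-Hartigan product-partition Gaussian
// change-point model on a 1-D signal x[0..n-1].
//
// Model: x_i ~ N(mu_i, s2); within a block of the partition the mean is
// drawn N(mu0, s02/m) for a block of m observations; priors are uniform on
// the change probability p in (0, p0] and on the variance ratio
// w = s2/(s2+s02) in (0, w0], with flat priors on mu0 and log s2.
// Integrating mu0 and s2 gives the partition marginal
//   f(rho | x) prop. Ip(b) * Iw(b, W, B)
//   Ip(b) = int_0^p0 p^(b-1) (1-p)^(n-b) dp
//   Iw    = int_0^w0 w^((b-1)/2) (W + w B)^(-(n-1)/2) dw
// with b blocks, W = within-block SS, B = between-block SS. Each Gibbs step
// toggles one change indicator using the exact conditional odds; both
// one-dimensional integrals are evaluated in closed incomplete-beta form,
// with a log-space Simpson fallback when the beta shape for Iw is invalid
// (small n). Per-sweep posterior bin means are the block means shrunk
// toward the overall mean by the conditional posterior mean of w.

#include <Rcpp.h>
#include <set>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log int_0^u t^(a-1) (1-t)^(c-1) dt  (incomplete beta, unnormalised)
static inline double log_inc_beta(double u, double a, double c) {
  return ::Rf_lbeta(a, c) + ::Rf_pbeta(u, a, c, 1, 1);
}

// log int_0^w0 w^a (W + B w)^(-nu) dw by composite Simpson in log space;
// used only when the closed form's beta shapes are invalid (small n).
static double log_iw_numeric(double a, double W, double B, double nu,
                             double w0) {
  const int K = 2000; // intervals (even)
  double h = w0 / K, m = NEG_INF;
  std::vector<double> lf(K + 1);
  for (int k = 0; k <= K; ++k) {
    double w = (k == 0) ? w0 * 1e-12 : k * h;
    double v = a * std::log(w) - nu * std::log(W + B * w);
    lf[k] = v;
    if (v > m) m = v;
  }
  if (!R_finite(m)) return NEG_INF;
  double s = 0.0;
  for (int k = 0; k <= K; ++k) {
    double wgt = (k == 0 || k == K) ? 1.0 : (k % 2 ? 4.0 : 2.0);
    s += wgt * std::exp(lf[k] - m);
  }
  return m + std::log(s * h / 3.0);
}

// log Iw(a; W, B) = log int_0^w0 w^a (W + B w)^(-(n-1)/2) dw
static double log_iw(double a, double W, double B, double nu, double w0) {
  const double tiny = 1e-300;
  if (B <= tiny && W <= tiny) {
    // constant data: the likelihood term cancels; int w^a dw
    return (a + 1.0) * std::log(w0) - std::log(a + 1.0);
  }
  if (B <= tiny) // single block / zero between-block SS
    return -nu * std::log(W) + (a + 1.0) * std::log(w0) - std::log(a + 1.0);
  if (W <= tiny) {
    double e = a - nu + 1.0;
    if (e > 0)
      return -nu * std::log(B) + e * std::log(w0) - std::log(e);
    W = tiny * B; // divergent at w=0: regularise
  }
  double c = nu - a - 1.0; // second beta shape
  if (c > 0) {
    double t0 = B * w0 / (W + B * w0);
    return (a + 1.0 - nu) * std::log(W) - (a + 1.0) * std::log(B) +
           log_inc_beta(t0, a + 1.0, c);
  }
  return log_iw_numeric(a, W, B, nu, w0);
}

struct BlockState {
  // change-point set: positions i in 1..n-1 meaning a boundary between
  // x[i-1] and x[i]; sentinels 0 and n always present.
  std::set<int> cp;
  std::vector<double> cs; // prefix sums, cs[k] = sum x[0..k-1]
  int n;
  double T; // sum over blocks of (block sum)^2 / m

  void init(const NumericVector& x) {
    n = x.size();
    cs.assign(n + 1, 0.0);
    for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
    cp.clear();
    cp.insert(0);
    cp.insert(n);
    T = cs[n] * cs[n] / n; // single block
  }
  inline double seg(int lo, int hi) const { return cs[hi] - cs[lo]; }
  inline double term(int lo, int hi) const {
    double s = seg(lo, hi);
    return s * s / (hi - lo);
  }
};

// [[Rcpp::export]]
List bcp_gibbs(NumericVector x, int iterations, int burnin, double p0,
               double w0) {
  int n = x.size();
  if (n < 3) stop("need at least 3 bins for the change-point model");
  for (int i = 0; i < n; ++i)
    if (!R_finite(x[i])) stop("non-finite z-score at bin %d", i + 1);
  if (p0 <= 0 || p0 > 1 || w0 <= 0 || w0 > 1)
    stop("p0 and w0 must lie in (0, 1]");

  BlockState st;
  st.init(x);
  double nu = (n - 1.0) / 2.0;
  double Q = 0.0, xbar = st.cs[n] / n;
  for (int i = 0; i < n; ++i) Q += x[i] * x[i];
  double nxbar2 = n * xbar * xbar;

  NumericVector post_mean(n, 0.0), prob(n - 1, 0.0);
  double sum_b = 0.0, sum_w = 0.0;
  int kept = 0, total = iterations + burnin;
  RNGScope scope;

  for (int sweep = 0; sweep < total; ++sweep) {
    for (int i = 1; i <= n - 1; ++i) {
      bool active = st.cp.count(i) > 0;
      // enclosing block boundaries ignoring i itself
      std::set<int>::iterator hi_it = st.cp.upper_bound(i);
      int hi = *hi_it;
      std::set<int>::iterator lo_it = hi_it;
      --lo_it;
      int lo = *lo_it;
      if (active) {
        --lo_it;
        lo = *lo_it;
      }
      // b0 = number of blocks when indicator at i is 0
      int b0 = (int)st.cp.size() - 1 - (active ? 1 : 0);
      double t_merged = st.term(lo, hi);
      double t_split = st.term(lo, i) + st.term(i, hi);
      double T0 = active ? st.T - t_split + t_merged : st.T;
      double T1 = T0 - t_merged + t_split;
      double W0 = Q - T0, B0 = T0 - nxbar2;
      double W1 = Q - T1, B1 = T1 - nxbar2;
      if (W0 < 0) W0 = 0;
      if (B0 < 0) B0 = 0;
      if (W1 < 0) W1 = 0;
      if (B1 < 0) B1 = 0;
      // prior (p) part: b0 -> b0+1 blocks
      double lp = log_inc_beta(p0, b0 + 1.0, (double)(n - b0)) -
                  log_inc_beta(p0, (double)b0, (double)(n - b0 + 1));
      // likelihood (w) part
      double lw = log_iw(b0 / 2.0, W1, B1, nu, w0) -
                  log_iw((b0 - 1.0) / 2.0, W0, B0, nu, w0);
      double lodds = lp + lw;
      double podds = (lodds > 35)    ? 1.0
                     : (lodds < -35) ? 0.0
                                     : std::exp(lodds) / (1.0 + std::exp(lodds));
      bool newstate = unif_rand() < podds;
      if (newstate != active) {
        if (newstate) {
          st.cp.insert(i);
          st.T = T1;
        } else {
          st.cp.erase(i);
          st.T = T0;
        }
      } else {
        st.T = newstate ? T1 : T0;
      }
    }
    if (sweep < burnin) continue;
    ++kept;
    int b = (int)st.cp.size() - 1;
    double W = Q - st.T, B = st.T - nxbar2;
    if (W < 0) W = 0;
    if (B < 0) B = 0;
    // conditional posterior mean of w given the partition
    double a = (b - 1.0) / 2.0;
    double lw_den = log_iw(a, W, B, nu, w0);
    double lw_num = log_iw(a + 1.0, W, B, nu, w0);
    double what = std::exp(lw_num - lw_den);
    if (!R_finite(what) || what < 0) what = 0;
    if (what > w0) what = w0;
    sum_w += what;
    sum_b += b;
    std::set<int>::iterator it = st.cp.begin();
    int lo = *it;
    ++it;
    for (; it != st.cp.end(); ++it) {
      int hi = *it;
      double bm = st.seg(lo, hi) / (hi - lo);
      double shrunk = xbar + (1.0 - what) * (bm - xbar);
      for (int k = lo; k < hi; ++k) post_mean[k] += shrunk;
      lo = hi;
    }
    for (std::set<int>::iterator c = st.cp.begin(); c != st.cp.end(); ++c)
      if (*c > 0 && *c < n) prob[*c - 1] += 1.0;
  }
  for (int k = 0; k < n; ++k) post_mean[k] /= kept;
  for (int k = 0; k < n - 1; ++k) prob[k] /= kept;
  return List::create(_["post_mean"] = post_mean, _["change_prob"] = prob,
                      _["mean_blocks"] = sum_b / kept,
                      _["mean_w"] = sum_w / kept, _["sweeps_kept"] = kept);
}
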