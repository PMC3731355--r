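#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- Breslow partial likelihood for a single covariate -------------------
//
// Samples must arrive sorted by increasing time; tied event times share one
// risk set (Breslow). A log-sum-exp shift over beta*x keeps the risk sums
// finite for large |beta| * range(x).

static void breslow_eval(const std::vector<double>& x,
                         const std::vector<double>& tm,
                         const std::vector<int>& ev,
                         double beta,
                         double& ll, double& U, double& I) {
  const int n = (int)x.size();
  double shift = -1e300;
  for (int i = 0; i < n; ++i) {
    double v = beta * x[i];
    if (v > shift) shift = v;
  }
  if (shift < 0.0) shift = 0.0;
  ll = 0.0; U = 0.0; I = 0.0;
  double S0 = 0.0, S1 = 0.0, S2 = 0.0;
  int k = n - 1;
  while (k >= 0) {
    int j = k;
    while (j >= 0 && tm[j] == tm[k]) {
      double e = std::exp(beta * x[j] - shift);
      S0 += e; S1 += x[j] * e; S2 += x[j] * x[j] * e;
      --j;
    }
    int d = 0; double sx = 0.0;
    for (int i = j + 1; i <= k; ++i) if (ev[i]) { ++d; sx += x[i]; }
    if (d > 0) {
      ll += beta * sx - d * (std::log(S0) + shift);
      double m1 = S1 / S0, m2 = S2 / S0;
      U += sx - d * m1;
      double v = m2 - m1 * m1;
      if (v < 0.0) v = 0.0;
      I += d * v;
    }
    k = j;
  }
}

struct CoxRes {
  double beta, ll0, ll1, lrt;
  bool converged, divergent;
};

// Safeguarded Newton ascent of the (concave) scalar Breslow partial
// log-likelihood; step-halving enforces monotone increase, |beta| capped to
// flag monotone-likelihood divergence.
static CoxRes cox_core(const std::vector<double>& xin,
                       const std::vector<double>& tm,
                       const std::vector<int>& ev,
                       double cap) {
  const int n = (int)xin.size();
  std::vector<double> x(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) mx += xin[i];
  mx /= n;
  double rng = 0.0;
  for (int i = 0; i < n; ++i) {
    x[i] = xin[i] - mx;
    if (std::fabs(x[i]) > rng) rng = std::fabs(x[i]);
  }
  CoxRes r; r.converged = false; r.divergent = false;
  double ll0, U0, I0;
  breslow_eval(x, tm, ev, 0.0, ll0, U0, I0);
  r.ll0 = ll0;
  if (rng == 0.0 || I0 <= 1e-12) {       // uninformative covariate
    r.beta = 0.0; r.ll1 = ll0; r.lrt = 0.0; r.converged = true;
    return r;
  }
  double beta = 0.0, ll = ll0, U = U0, I = I0;
  for (int it = 0; it < 100; ++it) {
    if (std::fabs(U) < 1e-11 * (1.0 + std::fabs(ll))) { r.converged = true; break; }
    double step;
    if (I > 1e-300) step = U / I; else step = (U > 0 ? 1.0 : -1.0);
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    double nb = beta + step;
    double nll, nU, nI;
    breslow_eval(x, tm, ev, nb, nll, nU, nI);
    int h = 0;
    while (nll < ll - 1e-12 && h < 50) {
      step *= 0.5; nb = beta + step;
      breslow_eval(x, tm, ev, nb, nll, nU, nI);
      ++h;
    }
    beta = nb; ll = nll; U = nU; I = nI;
    if (beta >= cap || beta <= -cap) {
      beta = (beta > 0 ? cap : -cap);
      breslow_eval(x, tm, ev, beta, ll, U, I);
      if ((beta > 0 && U > 0) || (beta < 0 && U < 0)) { r.divergent = true; break; }
    }
    if (std::fabs(step) < 1e-12) { r.converged = true; break; }
  }
  if (!r.converged && !r.divergent && std::fabs(U) < 1e-6) r.converged = true;
  r.beta = beta; r.ll1 = ll;
  r.lrt = 2.0 * (ll - ll0);
  if (r.lrt < 0.0) r.lrt = 0.0;
  return r;
}

// [[Rcpp::export]]
List cpp_cox_fit(NumericVector x, NumericVector time, IntegerVector event,
                 double beta_cap) {
  const int n = x.size();
  std::vector<double> xv(n), tv(n);
  std::vector<int> evv(n);
  for (int i = 0; i < n; ++i) { xv[i] = x[i]; tv[i] = time[i]; evv[i] = event[i]; }
  CoxRes r = cox_core(xv, tv, evv, beta_cap);
  return List::create(_["beta"] = r.beta,
                      _["loglik_at_zero"] = r.ll0,
                      _["loglik_at_beta"] = r.ll1,
                      _["lrt"] = r.lrt,
                      _["converged"] = r.converged,
                      _["divergent"] = r.divergent);
}

// Permutation scan of per-window burden scores against survival.
// burden: n_samples x n_windows; sidx: 1-based order(time); stime/sevent
// sorted ascending; permIdx: B x n, 1-based sample index feeding the
// covariate at each sorted slot. wgroup: 0-based window-size group id.
// [[Rcpp::export]]
List cpp_survival_scan(NumericMatrix burden, IntegerVector sidx,
                       NumericVector stime, IntegerVector sevent,
                       IntegerMatrix permIdx, IntegerVector wgroup,
                       double beta_cap) {
  const int n = stime.size();
  const int W = burden.ncol();
  const int B = permIdx.nrow();
  int G = 0;
  for (int w = 0; w < W; ++w) if (wgroup[w] + 1 > G) G = wgroup[w] + 1;

  std::vector<double> tv(n), xv(n);
  std::vector<int> evv(n);
  for (int i = 0; i < n; ++i) { tv[i] = stime[i]; evv[i] = sevent[i]; }

  NumericVector lrt_obs(W), beta_obs(W);
  LogicalVector div_obs(W), conv_obs(W);
  for (int w = 0; w < W; ++w) {
    for (int k = 0; k < n; ++k) xv[k] = burden(sidx[k] - 1, w);
    CoxRes r = cox_core(xv, tv, evv, beta_cap);
    lrt_obs[w] = r.lrt; beta_obs[w] = r.beta;
    div_obs[w] = r.divergent; conv_obs[w] = r.converged;
  }

  IntegerVector cnt_un(W), cnt_adj(W);
  std::vector<double> gmax(G), lrt_b(W);
  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < G; ++g) gmax[g] = -1.0;
    for (int w = 0; w < W; ++w) {
      for (int k = 0; k < n; ++k) xv[k] = burden(permIdx(b, k) - 1, w);
      CoxRes r = cox_core(xv, tv, evv, beta_cap);
      lrt_b[w] = r.lrt;
      if (r.lrt > gmax[wgroup[w]]) gmax[wgroup[w]] = r.lrt;
    }
    for (int w = 0; w < W; ++w) {
      if (lrt_b[w] >= lrt_obs[w]) ++cnt_un[w];
      if (gmax[wgroup[w]] >= lrt_obs[w]) ++cnt_adj[w];
    }
    if ((b & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["lrt"] = lrt_obs, _["beta"] = beta_obs,
                      _["divergent"] = div_obs, _["converged"] = conv_obs,
                      _["count_unadjusted"] = cnt_un,
                      _["count_adjusted"] = cnt_adj);
}

// Per-marker minor-allele frequency difference between groups, summed over
// contiguous windows via prefix sums. G: M x n minor-allele dosage matrix
// (NA for missing); markers all-missing within a group contribute 0.
static void dmaf_marker_diffs(const IntegerMatrix& G, const int* lab,
                              bool absolute, std::vector<double>& d) {
  const int M = G.nrow(), n = G.ncol();
  for (int m = 0; m < M; ++m) {
    int s1 = 0, c1 = 0, s0 = 0, c0 = 0;
    for (int i = 0; i < n; ++i) {
      int g = G(m, i);
      if (g == NA_INTEGER) continue;
      if (lab[i] == 1) { s1 += g; ++c1; } else { s0 += g; ++c0; }
    }
    if (c1 == 0 || c0 == 0) { d[m] = 0.0; continue; }
    double diff = (double)s1 / (2.0 * c1) - (double)s0 / (2.0 * c0);
    d[m] = absolute ? std::fabs(diff) : diff;
  }
}

// [[Rcpp::export]]
List cpp_dmaf_scan(IntegerMatrix G, IntegerVector grp, IntegerMatrix labMat,
                   IntegerVector wstart, IntegerVector wsize,
                   IntegerVector wgroup, bool absolute) {
  const int M = G.nrow(), n = G.ncol();
  const int W = wstart.size();
  const int B = labMat.nrow();
  int Gn = 0;
  for (int w = 0; w < W; ++w) if (wgroup[w] + 1 > Gn) Gn = wgroup[w] + 1;

  std::vector<double> d(M), cs(M + 1), cmp_obs(W);
  std::vector<int> lab(n);
  NumericVector stat_obs(W);

  for (int i = 0; i < n; ++i) lab[i] = grp[i];
  dmaf_marker_diffs(G, lab.data(), absolute, d);
  cs[0] = 0.0;
  for (int m = 0; m < M; ++m) cs[m + 1] = cs[m] + d[m];
  for (int w = 0; w < W; ++w) {
    double s = cs[wstart[w] - 1 + wsize[w]] - cs[wstart[w] - 1];
    stat_obs[w] = s;
    cmp_obs[w] = absolute ? s : std::fabs(s);
  }

  IntegerVector cnt_un(W), cnt_adj(W);
  std::vector<double> gmax(Gn), cmp_b(W);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) lab[i] = labMat(b, i);
    dmaf_marker_diffs(G, lab.data(), absolute, d);
    for (int m = 0; m < M; ++m) cs[m + 1] = cs[m] + d[m];
    for (int g = 0; g < Gn; ++g) gmax[g] = -1.0;
    for (int w = 0; w < W; ++w) {
      double s = cs[wstart[w] - 1 + wsize[w]] - cs[wstart[w] - 1];
      double c = absolute ? s : std::fabs(s);
      cmp_b[w] = c;
      if (c > gmax[wgroup[w]]) gmax[wgroup[w]] = c;
    }
    for (int w = 0; w < W; ++w) {
      if (cmp_b[w] >= cmp_obs[w]) ++cnt_un[w];
      if (gmax[wgroup[w]] >= cmp_obs[w]) ++cnt_adj[w];
    }
    if ((b & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["statistic"] = stat_obs,
                      _["count_unadjusted"] = cnt_un,
                      _["count_adjusted"] = cnt_adj);
}
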