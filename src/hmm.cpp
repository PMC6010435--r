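// Two-state IBD hidden Markov model: scaled forward log-likelihood and a
// bounded maximum-likelihood fitter over (f, a). f is the stationary
// probability that a marker is autozygous; a is the per-cM rate governing
// IBD segment turnover. Transitions over genetic distance d cM:
//   P(IBD -> IBD)    = e^{-a d} + (1 - e^{-a d}) f
//   P(nonIBD -> IBD) = (1 - e^{-a d}) f
// Chains restart at stationarity (f, 1 - f) on each chromosome. Emissions
// are precomputed per marker on the R side (eN = non-IBD, eI = IBD).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

static double forward_loglik(const double* eN, const double* eI,
                             const double* d, const int* newchrom,
                             int m, double f, double a) {
  double ll = 0.0, aI = 0.0, aN = 1.0;
  for (int i = 0; i < m; ++i) {
    double bI, bN;
    if (newchrom[i]) {
      bI = f * eI[i];
      bN = (1.0 - f) * eN[i];
    } else {
      double q = 1.0 - std::exp(-a * d[i]);  // prob. of segment turnover
      double pII = (1.0 - q) + q * f;
      double pNI = q * f;
      double nI = aI * pII + aN * pNI;
      double nN = aI * (1.0 - pII) + aN * (1.0 - pNI);
      bI = nI * eI[i];
      bN = nN * eN[i];
    }
    double s = bI + bN;
    if (s <= 0.0 || !std::isfinite(s))
      return -std::numeric_limits<double>::infinity();
    ll += std::log(s);
    aI = bI / s;
    aN = bN / s;
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_hmm_loglik(NumericVector eN, NumericVector eI, NumericVector d,
                      IntegerVector newchrom, double f, double a) {
  return forward_loglik(eN.begin(), eI.begin(), d.begin(), newchrom.begin(),
                        eN.size(), f, a);
}

// ---- bounded Nelder-Mead fitter ------------------------------------------

struct Bounds {
  double fl, fu, al, au;
};

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double logit(double p) { return std::log(p / (1.0 - p)); }

// parameters optimized on an unconstrained scale mapped log-logistically
// into [fl, fu] x [al, au]
static inline double y_to_f(double y, const Bounds& b) {
  return std::exp(std::log(b.fl) +
                  (std::log(b.fu) - std::log(b.fl)) * sigmoid(y));
}
static inline double y_to_a(double y, const Bounds& b) {
  return std::exp(std::log(b.al) +
                  (std::log(b.au) - std::log(b.al)) * sigmoid(y));
}
static inline double f_to_y(double f, const Bounds& b) {
  double t = (std::log(f) - std::log(b.fl)) / (std::log(b.fu) - std::log(b.fl));
  t = std::min(std::max(t, 1e-6), 1.0 - 1e-6);
  return logit(t);
}
static inline double a_to_y(double a, const Bounds& b) {
  double t = (std::log(a) - std::log(b.al)) / (std::log(b.au) - std::log(b.al));
  t = std::min(std::max(t, 1e-6), 1.0 - 1e-6);
  return logit(t);
}

struct NegLL {
  const double *eN, *eI, *d;
  const int* nw;
  int m;
  const Bounds& b;
  int evals = 0;
  double operator()(double y1, double y2) {
    ++evals;
    return -forward_loglik(eN, eI, d, nw, m, y_to_f(y1, b), y_to_a(y2, b));
  }
};

// standard Nelder-Mead on 2 parameters
static void nelder_mead(NegLL& obj, double y1, double y2, int maxit,
                        double tol, double* best_y, double* best_val) {
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  double px[3][2] = {{y1, y2}, {y1 + 0.7, y2}, {y1, y2 + 0.7}};
  double pv[3];
  for (int i = 0; i < 3; ++i) pv[i] = obj(px[i][0], px[i][1]);
  for (int it = 0; it < maxit; ++it) {
    int ord[3] = {0, 1, 2};
    std::sort(ord, ord + 3, [&](int i, int j) { return pv[i] < pv[j]; });
    int lo = ord[0], nh = ord[1], hi = ord[2];
    if (std::fabs(pv[hi] - pv[lo]) < tol) break;
    double cx = 0, cy = 0;
    for (int i = 0; i < 3; ++i)
      if (i != hi) { cx += px[i][0]; cy += px[i][1]; }
    cx /= 2.0; cy /= 2.0;
    double rx = cx + alpha * (cx - px[hi][0]);
    double ry = cy + alpha * (cy - px[hi][1]);
    double rv = obj(rx, ry);
    if (rv < pv[lo]) {
      double ex = cx + gamma * (rx - cx), ey = cy + gamma * (ry - cy);
      double ev = obj(ex, ey);
      if (ev < rv) { px[hi][0] = ex; px[hi][1] = ey; pv[hi] = ev; }
      else { px[hi][0] = rx; px[hi][1] = ry; pv[hi] = rv; }
    } else if (rv < pv[nh]) {
      px[hi][0] = rx; px[hi][1] = ry; pv[hi] = rv;
    } else {
      double kx = cx + rho * (px[hi][0] - cx), ky = cy + rho * (px[hi][1] - cy);
      double kv = obj(kx, ky);
      if (kv < pv[hi]) { px[hi][0] = kx; px[hi][1] = ky; pv[hi] = kv; }
      else {
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          px[i][0] = px[lo][0] + sigma * (px[i][0] - px[lo][0]);
          px[i][1] = px[lo][1] + sigma * (px[i][1] - px[lo][1]);
          pv[i] = obj(px[i][0], px[i][1]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (pv[i] < pv[lo]) lo = i;
  best_y[0] = px[lo][0];
  best_y[1] = px[lo][1];
  *best_val = pv[lo];
}

static NumericVector fit_one(const double* eN, const double* eI,
                             const double* d, const int* nw, int m,
                             NumericVector fstarts, NumericVector astarts,
                             const Bounds& b, int n_refine, int maxit,
                             double tol) {
  NegLL obj{eN, eI, d, nw, m, b};
  int ns = fstarts.size() * astarts.size();
  std::vector<double> sy1(ns), sy2(ns), sv(ns);
  int k = 0;
  for (int i = 0; i < fstarts.size(); ++i)
    for (int j = 0; j < astarts.size(); ++j) {
      sy1[k] = f_to_y(fstarts[i], b);
      sy2[k] = a_to_y(astarts[j], b);
      sv[k] = obj(sy1[k], sy2[k]);
      ++k;
    }
  std::vector<int> ord(ns);
  for (int i = 0; i < ns; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int i, int j) { return sv[i] < sv[j]; });
  double grid_best = sv[ord[0]];
  double best_val = grid_best;
  double best_y[2] = {sy1[ord[0]], sy2[ord[0]]};
  int nr = std::min(n_refine, ns);
  for (int r = 0; r < nr; ++r) {
    double y[2], v;
    nelder_mead(obj, sy1[ord[r]], sy2[ord[r]], maxit, tol, y, &v);
    if (v < best_val) { best_val = v; best_y[0] = y[0]; best_y[1] = y[1]; }
  }
  return NumericVector::create(
      _["f"] = y_to_f(best_y[0], b), _["a"] = y_to_a(best_y[1], b),
      _["logL"] = -best_val, _["logL_grid_best"] = -grid_best,
      _["n_evals"] = obj.evals);
}

// [[Rcpp::export]]
NumericVector cpp_fit_festim(NumericVector eN, NumericVector eI,
                             NumericVector d, IntegerVector newchrom,
                             NumericVector fstarts, NumericVector astarts,
                             double fl, double fu, double al, double au,
                             int n_refine, int maxit, double tol) {
  Bounds b{fl, fu, al, au};
  return fit_one(eN.begin(), eI.begin(), d.begin(), newchrom.begin(),
                 eN.size(), fstarts, astarts, b, n_refine, maxit, tol);
}

// Fit every submap (list of 1-based marker index vectors). cm/chrom give
// full-panel genetic positions; emissions are full-panel per-marker values.
// [[Rcpp::export]]
NumericMatrix cpp_fit_submaps(NumericVector eN, NumericVector eI,
                              NumericVector cm, IntegerVector chrom,
                              List submaps, NumericVector fstarts,
                              NumericVector astarts, double fl, double fu,
                              double al, double au, int n_refine, int maxit,
                              double tol) {
  Bounds b{fl, fu, al, au};
  int ns = submaps.size();
  NumericMatrix out(ns, 4);
  colnames(out) = CharacterVector::create("f", "a", "logL", "logL0");
  for (int s = 0; s < ns; ++s) {
    IntegerVector idx = submaps[s];
    int m = idx.size();
    std::vector<double> seN(m), seI(m), sd(m);
    std::vector<int> nw(m);
    double ll0 = 0.0;
    for (int i = 0; i < m; ++i) {
      int j = idx[i] - 1;
      seN[i] = eN[j];
      seI[i] = eI[j];
      if (i == 0 || chrom[j] != chrom[idx[i - 1] - 1]) {
        nw[i] = 1;
        sd[i] = 0.0;
      } else {
        nw[i] = 0;
        sd[i] = cm[j] - cm[idx[i - 1] - 1];
      }
      ll0 += std::log(seN[i]);
    }
    NumericVector r = fit_one(seN.data(), seI.data(), sd.data(), nw.data(),
                              m, fstarts, astarts, b, n_refine, maxit, tol);
    out(s, 0) = r["f"];
    out(s, 1) = r["a"];
    out(s, 2) = r["logL"];
    out(s, 3) = ll0;  // null log-likelihood at f = 0 on this submap
  }
  return out;
}
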