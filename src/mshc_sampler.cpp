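#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Conditional log-intensity of a point (x, y) of type m given the current
// state, excluding the point at index `skip` (-1 for none).  Interaction
// matrices are passed squared (h2, r2); inactive pairs carry the sentinel -1
// so the comparison d2 <= h2 can never fire.  Returns -Inf when a hard core
// is violated or a gamma = 0 annulus is occupied.
static double log_cif(double x, double y, int m,
                      const std::vector<double>& px,
                      const std::vector<double>& py,
                      const std::vector<int>& pt,
                      int skip,
                      const NumericVector& logbeta,
                      const NumericMatrix& h2,
                      const NumericMatrix& r2,
                      const NumericMatrix& loggam,
                      const List& covref,
                      const NumericMatrix& covcoef) {
  double lc = logbeta[m];
  const int n = (int) px.size();
  for (int j = 0; j < n; ++j) {
    if (j == skip) continue;
    const double dx = px[j] - x, dy = py[j] - y;
    const double d2 = dx * dx + dy * dy;
    const int tj = pt[j];
    if (d2 <= h2(m, tj)) return R_NegInf;
    if (d2 <= r2(m, tj)) {
      const double lg = loggam(m, tj);
      if (lg == R_NegInf) return R_NegInf;  // gamma == 0: forbidden annulus
      lc += lg;
    }
  }
  const int ncov = covref.size();
  for (int c = 0; c < ncov; ++c) {
    const double coef = covcoef(m, c);
    if (coef == 0.0) continue;
    NumericMatrix refs = covref[c];
    double best = R_PosInf;
    for (int k = 0; k < refs.nrow(); ++k) {
      const double dx = refs(k, 0) - x, dy = refs(k, 1) - y;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    lc += coef * std::sqrt(best);
  }
  return lc;
}

// Birth/death/shift Metropolis-Hastings sampler for the multitype Strauss
// hard-core model.  When fixed_n is true only shift moves are proposed, so the
// per-type point counts of the initial state are preserved and the chain
// targets the model conditioned on those counts.  Uses R's RNG, so runs are
// reproducible under set.seed().
// [[Rcpp::export]]
List mshc_mh_cpp(NumericVector xr, NumericVector yr,
                 NumericVector logbeta,
                 NumericMatrix h2, NumericMatrix r2, NumericMatrix loggam,
                 List covref, NumericMatrix covcoef,
                 NumericVector init_x, NumericVector init_y,
                 IntegerVector init_t,
                 int nprop, double p_birth, double p_death,
                 bool fixed_n, int cap) {
  const double x0 = xr[0], x1 = xr[1], y0 = yr[0], y1 = yr[1];
  const double area = (x1 - x0) * (y1 - y0);
  const int M = logbeta.size();

  std::vector<double> px(init_x.begin(), init_x.end());
  std::vector<double> py(init_y.begin(), init_y.end());
  std::vector<int> pt(init_t.begin(), init_t.end());

  RNGScope scope;

  for (int it = 0; it < nprop; ++it) {
    const int n = (int) px.size();
    double move = fixed_n ? (p_birth + p_death) : unif_rand();
    if (!fixed_n && move < p_birth) {
      // birth
      const double x = x0 + unif_rand() * (x1 - x0);
      const double y = y0 + unif_rand() * (y1 - y0);
      const int m = (int) std::floor(unif_rand() * M);
      const double lc = log_cif(x, y, m, px, py, pt, -1, logbeta,
                                h2, r2, loggam, covref, covcoef);
      if (lc == R_NegInf) continue;
      const double a = std::exp(lc) * area * M / (double)(n + 1);
      if (unif_rand() < a) {
        px.push_back(x); py.push_back(y); pt.push_back(m);
        if ((int) px.size() > cap)
          stop("simulated pattern exceeded the safety cap (%d points); "
               "the model appears non-integrable or poorly scaled", cap);
      }
    } else if (!fixed_n && move < p_birth + p_death) {
      // death
      if (n == 0) continue;
      const int i = (int) std::floor(unif_rand() * n);
      const double lc = log_cif(px[i], py[i], pt[i], px, py, pt, i, logbeta,
                                h2, r2, loggam, covref, covcoef);
      const double a = (double) n / (std::exp(lc) * area * M);
      if (unif_rand() < a) {
        px[i] = px.back(); py[i] = py.back(); pt[i] = pt.back();
        px.pop_back(); py.pop_back(); pt.pop_back();
      }
    } else {
      // shift (type-preserving); single-pass log-ratio of conditional
      // intensities at the new vs old location
      if (n == 0) continue;
      const int i = (int) std::floor(unif_rand() * n);
      const double x = x0 + unif_rand() * (x1 - x0);
      const double y = y0 + unif_rand() * (y1 - y0);
      const int m = pt[i];
      const double xi = px[i], yi = py[i];
      double dlog = 0.0;
      bool ok = true;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const int tj = pt[j];
        const double r2mj = r2(m, tj);
        if (r2mj < 0) continue;  // inactive pair
        double dx = px[j] - x, dy = py[j] - y;
        const double d2new = dx * dx + dy * dy;
        if (d2new <= r2mj) {
          if (d2new <= h2(m, tj)) { ok = false; break; }
          const double lg = loggam(m, tj);
          if (lg == R_NegInf) { ok = false; break; }
          dlog += lg;
        }
        dx = px[j] - xi; dy = py[j] - yi;
        const double d2old = dx * dx + dy * dy;
        if (d2old <= r2mj && d2old > h2(m, tj)) dlog -= loggam(m, tj);
      }
      if (!ok) continue;
      const int ncov = covref.size();
      for (int c = 0; c < ncov; ++c) {
        const double coefc = covcoef(m, c);
        if (coefc == 0.0) continue;
        NumericMatrix refs = covref[c];
        double bnew = R_PosInf, bold = R_PosInf;
        for (int k = 0; k < refs.nrow(); ++k) {
          double dx = refs(k, 0) - x, dy = refs(k, 1) - y;
          double d2 = dx * dx + dy * dy;
          if (d2 < bnew) bnew = d2;
          dx = refs(k, 0) - xi; dy = refs(k, 1) - yi;
          d2 = dx * dx + dy * dy;
          if (d2 < bold) bold = d2;
        }
        dlog += coefc * (std::sqrt(bnew) - std::sqrt(bold));
      }
      if (std::log(unif_rand()) < dlog) {
        px[i] = x; py[i] = y;
      }
    }
  }

  return List::create(_["x"] = NumericVector(px.begin(), px.end()),
                      _["y"] = NumericVector(py.begin(), py.end()),
                      _["type"] = IntegerVector(pt.begin(), pt.end()));
}
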