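#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simplex-projection cross-map prediction.
//
// M:            manifold points (rows) x embedding dimension (cols)
// target_vals:  scalar value to predict, aligned with the rows of M
// times:        integer time stamp of each row (used for the Theiler
//               exclusion window; rows from different segments carry
//               well-separated stamps)
// lib, pred:    1-based row indices of library and prediction points
// k:            number of neighbours (E + 1 for simplex projection)
// theiler:      rows with |time - time(pred)| <= theiler are excluded,
//               which also excludes the prediction point itself
// uniform:      if true, use uniform weights instead of the exponential
//               simplex weighting
//
// Returns predictions for each pred row (NA when fewer than k admissible
// neighbours exist). Neighbour search is a single pass keeping the k best
// squared distances (k is tiny, so insertion into the running top-k is
// cheaper than sorting).
// [[Rcpp::export]]
NumericVector simplex_predict_cpp(NumericMatrix M, NumericVector target_vals,
                                  IntegerVector times, IntegerVector lib,
                                  IntegerVector pred, int k, int theiler,
                                  bool uniform) {
  const int E = M.ncol();
  const int N = M.nrow();
  const int nl = lib.size();
  const int np = pred.size();
  NumericVector out(np, NA_REAL);

  // column-major access: cache pointers per dimension
  std::vector<const double*> col(E);
  for (int e = 0; e < E; ++e) col[e] = &M(0, e);

  std::vector<double> bestd(k);
  std::vector<int> besti(k);

  for (int p = 0; p < np; ++p) {
    const int tp = pred[p] - 1;
    const int tt = times[tp];
    int found = 0;
    double worst = R_PosInf;
    for (int l = 0; l < nl; ++l) {
      const int tl = lib[l] - 1;
      if (std::abs(times[tl] - tt) <= theiler) continue;
      double s = 0.0;
      for (int e = 0; e < E; ++e) {
        const double diff = col[e][tp] - col[e][tl];
        s += diff * diff;
      }
      if (found < k) {
        // insert into the (still short) top-k list
        int pos = found++;
        while (pos > 0 && bestd[pos - 1] > s) {
          bestd[pos] = bestd[pos - 1];
          besti[pos] = besti[pos - 1];
          --pos;
        }
        bestd[pos] = s;
        besti[pos] = tl;
        worst = bestd[found - 1];
      } else if (s < worst) {
        int pos = k - 1;
        while (pos > 0 && bestd[pos - 1] > s) {
          bestd[pos] = bestd[pos - 1];
          besti[pos] = besti[pos - 1];
          --pos;
        }
        bestd[pos] = s;
        besti[pos] = tl;
        worst = bestd[k - 1];
      }
    }
    if (found < k) continue;
    const double dmin = std::sqrt(bestd[0]);
    double wsum = 0.0, est = 0.0;
    for (int i = 0; i < k; ++i) {
      double w;
      if (uniform) {
        w = 1.0;
      } else if (dmin <= 0.0) {
        // exact matches on the manifold: weight only the ties at zero
        w = (bestd[i] <= 0.0) ? 1.0 : 0.0;
      } else {
        w = std::exp(-std::sqrt(bestd[i]) / dmin);
      }
      wsum += w;
      est += w * target_vals[besti[i]];
    }
    if (wsum > 0.0) out[p] = est / wsum;
  }
  (void)N;
  return out;
}
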