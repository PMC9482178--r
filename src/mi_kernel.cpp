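#include <Rcpp.h>
using namespace Rcpp;

// Pairwise entropy / joint-entropy / MI / adjusted-MI over a matrix of
// discretized taxon profiles. `labels` holds 1-based bin labels (n samples
// x m taxa); `nlev` the number of bins per taxon. All entropies in nats.
//
// MI is computed as H(X) + H(Y) - H(X,Y); exact counting means negatives can
// only arise from floating point, so values in (-1e-9, 0) are clamped to 0
// and anything more negative aborts (internal inconsistency).
// Adjusted MI divides by the pair's joint entropy; a pair of two constant
// taxa (joint entropy 0) is defined to share nothing (0 off-diagonal).
// [[Rcpp::export]]
List cpp_mi_components(const IntegerMatrix& labels, const IntegerVector& nlev) {
  const int n = labels.nrow(), m = labels.ncol();
  if (n < 1 || m < 1) stop("empty label matrix");
  NumericVector H(m);
  NumericMatrix Hj(m, m), MI(m, m), A(m, m);
  const double logn = std::log((double)n);

  for (int j = 0; j < m; ++j) {
    std::vector<int> cnt(nlev[j], 0);
    for (int i = 0; i < n; ++i) {
      int l = labels(i, j);
      if (l < 1 || l > nlev[j]) stop("bin label out of range in column %d", j + 1);
      cnt[l - 1]++;
    }
    double h = 0.0;
    for (int c : cnt)
      if (c > 0) h -= ((double)c / n) * (std::log((double)c) - logn);
    H[j] = h < 0 ? 0.0 : h;
  }

  std::vector<int> joint;
  for (int j = 0; j < m; ++j) {
    Hj(j, j) = H[j];
    MI(j, j) = H[j];
    A(j, j) = 1.0;
    for (int jp = j + 1; jp < m; ++jp) {
      const int Lp = nlev[jp];
      joint.assign((size_t)nlev[j] * Lp, 0);
      for (int i = 0; i < n; ++i)
        joint[(size_t)(labels(i, j) - 1) * Lp + (labels(i, jp) - 1)]++;
      double h = 0.0;
      for (int c : joint)
        if (c > 0) h -= ((double)c / n) * (std::log((double)c) - logn);
      double mi = H[j] + H[jp] - h;
      if (mi < 0) {
        if (mi < -1e-9)
          stop("negative mutual information beyond tolerance (columns %d, %d)",
               j + 1, jp + 1);
        mi = 0.0;
      }
      double a = (h > 0.0) ? mi / h : 0.0;
      if (a < 0) a = 0.0;
      if (a > 1) a = 1.0;  // fp guard; MI <= joint entropy analytically
      Hj(j, jp) = Hj(jp, j) = h;
      MI(j, jp) = MI(jp, j) = mi;
      A(j, jp) = A(jp, j) = a;
    }
  }
  return List::create(_["H"] = H, _["Hjoint"] = Hj, _["mi"] = MI,
                      _["adjusted"] = A);
}
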