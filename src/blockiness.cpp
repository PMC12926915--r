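#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Patterning statistic delta for all 8x8 class pairs of one arrangement.
//
// cls: 0-based-shifted class index per position (1..8, 0 = unclassified).
// For pair (a,b), a!=b: sigma = (f+ - f-)^2 / (f+ + f-) over a window
// (0 when the window holds neither class); diagonal: sigma = class fraction.
// delta(a,b) = mean over windows of (sigma_win - sigma_seq)^2, averaged
// over the supplied window sizes.
static void delta_all_pairs(const std::vector<int>& cls,
                            const IntegerVector& wins,
                            double out[8][8]) {
  const int L = (int)cls.size();
  // global class fractions
  double ftot[9] = {0};
  for (int i = 0; i < L; ++i) ftot[cls[i]] += 1.0;
  for (int k = 0; k <= 8; ++k) ftot[k] /= L;

  double sigma_seq[8][8];
  for (int a = 0; a < 8; ++a) {
    for (int b = 0; b < 8; ++b) {
      if (a == b) {
        sigma_seq[a][b] = ftot[a + 1];
      } else {
        double s = ftot[a + 1] + ftot[b + 1];
        sigma_seq[a][b] = s > 0 ? (ftot[a + 1] - ftot[b + 1]) *
                                      (ftot[a + 1] - ftot[b + 1]) / s
                                : 0.0;
      }
    }
  }

  double acc[8][8] = {{0}};
  int used = 0;
  for (int wi = 0; wi < wins.size(); ++wi) {
    const int w = wins[wi];
    if (w > L) continue;
    ++used;
    const int nwin = L - w + 1;
    double sum[8][8] = {{0}};
    int cnt[9] = {0};
    for (int i = 0; i < w; ++i) cnt[cls[i]]++;
    for (int t = 0;; ++t) {
      for (int a = 0; a < 8; ++a) {
        const double fa = (double)cnt[a + 1] / w;
        // diagonal
        double d = fa - sigma_seq[a][a];
        sum[a][a] += d * d;
        for (int b = a + 1; b < 8; ++b) {
          const double fb = (double)cnt[b + 1] / w;
          const double tot = fa + fb;
          const double sig = tot > 0 ? (fa - fb) * (fa - fb) / tot : 0.0;
          double dd = sig - sigma_seq[a][b];
          sum[a][b] += dd * dd;
        }
      }
      if (t + 1 >= nwin) break;
      cnt[cls[t]]--;
      cnt[cls[t + w]]++;
    }
    for (int a = 0; a < 8; ++a)
      for (int b = a; b < 8; ++b)
        acc[a][b] += sum[a][b] / nwin;
  }
  for (int a = 0; a < 8; ++a)
    for (int b = a; b < 8; ++b) {
      out[a][b] = acc[a][b] / used;
      out[b][a] = out[a][b];
    }
}

// [[Rcpp::export]]
NumericMatrix blockiness_core(IntegerVector class_idx, int n_scrambles,
                              IntegerVector window_sizes) {
  const int L = class_idx.size();
  std::vector<int> cls(L);
  for (int i = 0; i < L; ++i) cls[i] = class_idx[i];

  double obs[8][8];
  delta_all_pairs(cls, window_sizes, obs);

  double sum[8][8] = {{0}}, sumsq[8][8] = {{0}};
  std::vector<int> perm(cls);
  RNGScope scope;  // scramble stream driven by R's RNG (set.seed upstream)
  for (int s = 0; s < n_scrambles; ++s) {
    // Fisher-Yates shuffle
    for (int i = L - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double d[8][8];
    delta_all_pairs(perm, window_sizes, d);
    for (int a = 0; a < 8; ++a)
      for (int b = a; b < 8; ++b) {
        sum[a][b] += d[a][b];
        sumsq[a][b] += d[a][b] * d[a][b];
      }
  }

  NumericMatrix z(8, 8);
  for (int a = 0; a < 8; ++a)
    for (int b = a; b < 8; ++b) {
      const double m = sum[a][b] / n_scrambles;
      double var = (sumsq[a][b] - n_scrambles * m * m) / (n_scrambles - 1);
      if (var < 0) var = 0;
      const double sdv = std::sqrt(var);
      double zz = 0.0;
      if (sdv > 0) zz = (obs[a][b] - m) / sdv;
      if (!R_finite(zz)) zz = 0.0;
      z(a, b) = zz;
      z(b, a) = zz;
    }
  return z;
}
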