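#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Batch GLCM texture extraction. For each candidate centre: extract the
// reflect-padded window, quantize it to `levels` gray levels by its own
// min-max range, build the symmetric normalized co-occurrence matrix for
// d = 1 at 0/45/90/135 degrees, and compute the 14 statistics. Output is
// feature-major: column (f * 4 + a) holds feature f at angle a, matching
// the R reference path in texture.R.

static inline int reflect_idx(int i, int n) {
  // 0-based half-sample reflection into [0, n)
  if (n == 1) return 0;
  int period = 2 * n;
  i = std::abs(i) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

static void glcm_features(const std::vector<double>& P, int G, double* out) {
  // P is the normalized symmetric GLCM (row-major G x G); out has room for 14
  std::vector<double> px(G, 0.0);
  for (int i = 0; i < G; ++i)
    for (int j = 0; j < G; ++j) px[i] += P[i * G + j];
  double mu = 0.0, va = 0.0;
  for (int i = 0; i < G; ++i) mu += i * px[i];
  for (int i = 0; i < G; ++i) va += (i - mu) * (i - mu) * px[i];

  double contrast = 0, homog = 0, energy = 0, corr_num = 0, shade = 0,
         prom = 0, idm = 0, entropy = 0;
  std::vector<double> psum(2 * G - 1, 0.0), pdiff(G, 0.0);
  for (int i = 0; i < G; ++i) {
    for (int j = 0; j < G; ++j) {
      double p = P[i * G + j];
      if (p == 0.0) continue;
      int dij = i - j;
      double s = i + j - 2.0 * mu;
      contrast += dij * dij * p;
      homog += p / (1.0 + std::abs(dij));
      energy += p * p;
      corr_num += static_cast<double>(i) * j * p;
      shade += s * s * s * p;
      prom += s * s * s * s * p;
      idm += p / (1.0 + dij * dij);
      entropy -= p * std::log(p);
      psum[i + j] += p;
      pdiff[std::abs(dij)] += p;
    }
  }
  double sum_avg = 0, sum_ent = 0, diff_ent = 0, mu_d = 0, diff_var = 0;
  for (int k = 0; k < 2 * G - 1; ++k) {
    sum_avg += k * psum[k];
    if (psum[k] > 0) sum_ent -= psum[k] * std::log(psum[k]);
  }
  for (int k = 0; k < G; ++k) {
    mu_d += k * pdiff[k];
    if (pdiff[k] > 0) diff_ent -= pdiff[k] * std::log(pdiff[k]);
  }
  for (int k = 0; k < G; ++k) diff_var += (k - mu_d) * (k - mu_d) * pdiff[k];

  out[0] = contrast;
  out[1] = homog;
  out[2] = energy;
  out[3] = va > 0 ? (corr_num - mu * mu) / va : 0.0;
  out[4] = shade;
  out[5] = prom;
  out[6] = idm;
  out[7] = entropy;
  out[8] = mu;
  out[9] = va;
  out[10] = sum_avg;
  out[11] = sum_ent;
  out[12] = diff_ent;
  out[13] = diff_var;
}

// [[Rcpp::export]]
NumericMatrix glcm_features_batch(NumericMatrix img, IntegerVector rows,
                                  IntegerVector cols, int window, int levels) {
  const int n = rows.size();
  const int nr = img.nrow(), nc = img.ncol();
  const int h = window / 2;
  // angle offsets (drow, dcol): 0, 45, 90, 135 degrees
  const int drs[4] = {0, -1, -1, -1};
  const int dcs[4] = {1, 1, 0, -1};

  NumericMatrix out(n, 56);
  std::vector<double> win(window * window);
  std::vector<int> q(window * window);
  std::vector<double> P(levels * levels);
  double feats[14];

  for (int c = 0; c < n; ++c) {
    int r0 = rows[c] - 1, c0 = cols[c] - 1;  // 0-based centre
    if (r0 < 0 || r0 >= nr || c0 < 0 || c0 >= nc)
      stop("candidate centre outside image");
    // window rows r0-h .. r0+h-1, reflect at borders (row-major within win)
    double lo = R_PosInf, hi = R_NegInf;
    for (int wr = 0; wr < window; ++wr) {
      int ir = reflect_idx(r0 - h + wr, nr);
      for (int wc = 0; wc < window; ++wc) {
        int ic = reflect_idx(c0 - h + wc, nc);
        double v = img(ir, ic);
        win[wr * window + wc] = v;
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
    }
    if (hi <= lo) {
      std::fill(q.begin(), q.end(), 0);
    } else {
      for (int k = 0; k < window * window; ++k) {
        int lv = static_cast<int>(std::floor((win[k] - lo) / (hi - lo) * levels));
        if (lv >= levels) lv = levels - 1;
        q[k] = lv;
      }
    }
    for (int a = 0; a < 4; ++a) {
      std::fill(P.begin(), P.end(), 0.0);
      int dr = drs[a], dc = dcs[a];
      double total = 0.0;
      for (int wr = 0; wr < window; ++wr) {
        int wr2 = wr + dr;
        if (wr2 < 0 || wr2 >= window) continue;
        for (int wc = 0; wc < window; ++wc) {
          int wc2 = wc + dc;
          if (wc2 < 0 || wc2 >= window) continue;
          int gi = q[wr * window + wc], gj = q[wr2 * window + wc2];
          P[gi * levels + gj] += 1.0;
          P[gj * levels + gi] += 1.0;  // symmetric counting
          total += 2.0;
        }
      }
      if (total > 0) {
        for (int k = 0; k < levels * levels; ++k) P[k] /= total;
      }
      glcm_features(P, levels, feats);
      for (int f = 0; f < 14; ++f) out(c, f * 4 + a) = feats[f];
    }
  }
  return out;
}
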