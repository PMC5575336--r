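#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Five association measures used by the ensemble, in the fixed order
//   0 spearman, 1 pearson, 2 mi, 3 braycurtis, 4 kl
// shared with the R layer (ng_measures()).  All kernels take plain sample
// vectors; ranking / binning is recomputed inside so the same code path
// serves observed, permuted and bootstrap-resampled data.

static const int N_MEASURES = 5;

// mid-ranks (ties averaged), 1-based
static void midrank(const std::vector<double>& x, std::vector<double>& r) {
  const int n = x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    const double avg = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
}

static double pearson_raw(const std::vector<double>& x,
                          const std::vector<double>& y) {
  const int n = x.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

static double spearman_raw(const std::vector<double>& x,
                           const std::vector<double>& y) {
  const int n = x.size();
  std::vector<double> rx(n), ry(n);
  midrank(x, rx);
  midrank(y, ry);
  return pearson_raw(rx, ry);
}

// Bray-Curtis dissimilarity sum|x-y| / sum(x+y)
static double braycurtis_raw(const std::vector<double>& x,
                             const std::vector<double>& y) {
  double num = 0, den = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    num += std::fabs(x[i] - y[i]);
    den += x[i] + y[i];
  }
  if (den <= 0) return NA_REAL;
  return num / den;
}

// symmetrized Kullback-Leibler divergence on Laplace-smoothed profiles
// p_i = (x_i + 1) / (sum(x) + n)
static double klsym_raw(const std::vector<double>& x,
                        const std::vector<double>& y) {
  const int n = x.size();
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) { sx += x[i]; sy += y[i]; }
  double kl_pq = 0, kl_qp = 0;
  for (int i = 0; i < n; ++i) {
    const double p = (x[i] + 1.0) / (sx + n);
    const double q = (y[i] + 1.0) / (sy + n);
    kl_pq += p * std::log(p / q);
    kl_qp += q * std::log(q / p);
  }
  return 0.5 * (kl_pq + kl_qp);
}

// equal-frequency bin labels, B bins, ties broken by original index so the
// assignment is deterministic on resampled (duplicated) values
static void eqfreq_bins(const std::vector<double>& x, int B,
                        std::vector<int>& bin) {
  const int n = x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  for (int pos = 0; pos < n; ++pos) {
    int b = (int)((long long)pos * B / n);
    if (b >= B) b = B - 1;
    bin[ord[pos]] = b;
  }
}

// mutual information (nats) on equal-frequency discretized vectors,
// B = floor(sqrt(n))
static double mi_raw(const std::vector<double>& x,
                     const std::vector<double>& y) {
  const int n = x.size();
  int B = (int)std::floor(std::sqrt((double)n));
  if (B < 2) B = 2;
  std::vector<int> bx(n), by(n);
  eqfreq_bins(x, B, bx);
  eqfreq_bins(y, B, by);
  std::vector<double> joint(B * B, 0.0), px(B, 0.0), py(B, 0.0);
  for (int i = 0; i < n; ++i) {
    joint[bx[i] * B + by[i]] += 1.0;
    px[bx[i]] += 1.0;
    py[by[i]] += 1.0;
  }
  double mi = 0;
  for (int a = 0; a < B; ++a)
    for (int b = 0; b < B; ++b) {
      const double pj = joint[a * B + b] / n;
      if (pj > 0) mi += pj * std::log(pj / ((px[a] / n) * (py[b] / n)));
    }
  return mi;
}

static void all_measures(const std::vector<double>& x,
                         const std::vector<double>& y, double* out) {
  out[0] = spearman_raw(x, y);
  out[1] = pearson_raw(x, y);
  out[2] = mi_raw(x, y);
  out[3] = braycurtis_raw(x, y);
  out[4] = klsym_raw(x, y);
}

static double one_measure(const std::vector<double>& x,
                          const std::vector<double>& y, int m) {
  switch (m) {
    case 0: return spearman_raw(x, y);
    case 1: return pearson_raw(x, y);
    case 2: return mi_raw(x, y);
    case 3: return braycurtis_raw(x, y);
    default: return klsym_raw(x, y);
  }
}

// [[Rcpp::export]]
NumericVector cpp_pair_scores(NumericVector x, NumericVector y) {
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  NumericVector out(N_MEASURES);
  all_measures(vx, vy, REAL(out));
  return out;
}

// Symmetric all-pairs score matrix for one measure; OTUs in rows.
// measure index follows the fixed order above.
// [[Rcpp::export]]
NumericMatrix cpp_score_matrix(NumericMatrix mat, int measure) {
  const int p = mat.nrow(), n = mat.ncol();
  std::vector<std::vector<double> > rows(p, std::vector<double>(n));
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < n; ++j) rows[i][j] = mat(i, j);
  NumericMatrix out(p, p);
  for (int i = 0; i < p; ++i) out(i, i) = NA_REAL;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      const double s = one_measure(rows[i], rows[j], measure);
      out(i, j) = s;
      out(j, i) = s;
    }
  return out;
}

// Fisher-Yates shuffle driven by R's RNG (so set.seed() governs everything)
static void shuffle_into(const std::vector<double>& src,
                         std::vector<double>& dst) {
  const int n = src.size();
  dst = src;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(dst[i], dst[j]);
  }
}

// Observed scores, permutation-null scores (one shared shuffle of y per
// iteration across all five measures, so cross-measure dependence is
// estimable), and bootstrap scores (samples resampled with replacement;
// iterations with fewer than min_distinct distinct samples are redrawn,
// capped at max_retry attempts).
// [[Rcpp::export]]
List cpp_edge_stats(NumericVector x, NumericVector y, int n_perm,
                    int n_boot, int min_distinct = 3, int max_retry = 100) {
  const int n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());

  NumericVector obs(N_MEASURES);
  all_measures(vx, vy, REAL(obs));

  NumericMatrix nullmat(n_perm, N_MEASURES);
  std::vector<double> yp;
  double sc[N_MEASURES];
  for (int it = 0; it < n_perm; ++it) {
    shuffle_into(vy, yp);
    all_measures(vx, yp, sc);
    for (int m = 0; m < N_MEASURES; ++m) nullmat(it, m) = sc[m];
  }

  NumericMatrix bootmat(n_boot, N_MEASURES);
  std::vector<double> bx(n), by(n);
  std::vector<int> idx(n), seen(n);
  for (int it = 0; it < n_boot; ++it) {
    int tries = 0, distinct = 0;
    do {
      std::fill(seen.begin(), seen.end(), 0);
      distinct = 0;
      for (int k = 0; k < n; ++k) {
        int j = (int)(unif_rand() * n);
        if (j >= n) j = n - 1;
        idx[k] = j;
        if (!seen[j]) { seen[j] = 1; ++distinct; }
      }
      ++tries;
    } while (distinct < min_distinct && tries < max_retry);
    for (int k = 0; k < n; ++k) { bx[k] = vx[idx[k]]; by[k] = vy[idx[k]]; }
    all_measures(bx, by, sc);
    for (int m = 0; m < N_MEASURES; ++m) bootmat(it, m) = sc[m];
  }

  return List::create(_["obs"] = obs, _["null"] = nullmat,
                      _["boot"] = bootmat);
}
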