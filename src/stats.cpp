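// Recombination summary statistics on binary haplotype matrices, with a
// bitset engine so that thousands of n-tuple subsamples can be scored
// quickly. Statistics with vanishing denominators are returned as NA
// (undefined) rather than 0; Hudson's C uses the 0 / cmax clamp rules.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

typedef std::vector<uint64_t> Bits;

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

inline int popcount(const Bits &b) {
  int c = 0;
  for (size_t i = 0; i < b.size(); ++i) c += popcount64(b[i]);
  return c;
}

inline int popcount_and(const Bits &a, const Bits &b) {
  int c = 0;
  for (size_t i = 0; i < a.size(); ++i) c += popcount64(a[i] & b[i]);
  return c;
}

// variance of the locus-average pair coalescence time given total scaled
// recombination C, from the two-locus covariance (y+18)/(y^2+13y+18):
// sigma2(C) = (2/C^2) * int_0^C (C-y) h(y) dy, closed form by partial
// fractions with sqrt(97); sigma2(0) = 1.
double pair_time_variance(double C) {
  if (C < 1e-9) return 1.0;
  const double s = std::sqrt(97.0);
  const double a = (-13.0 + s) / 2.0, b = (-13.0 - s) / 2.0;
  const double A = (a + 18.0) / s, B = -(b + 18.0) / s;
  double la = std::log((C - a) / (-a));
  double lb = std::log((C - b) / (-b));
  double ih = A * la + B * lb;              // int h
  double iyh = C + A * a * la + B * b * lb; // int y h
  return 2.0 * (C * ih - iyh) / (C * C);
}

double sksq_expect(double C, double thetahat) {
  return thetahat + thetahat * thetahat * pair_time_variance(C);
}

// moment estimator of the population recombination rate: solve
// E[Sk^2 | C] = observed Sk^2 (decreasing in C) by bisection on [0, cmax].
double hudsons_c_solve(double thetahat, double sksq, double cmax) {
  if (thetahat <= 0.0) return 0.0;
  if (sksq >= sksq_expect(0.0, thetahat)) return 0.0;
  if (sksq <= sksq_expect(cmax, thetahat)) return cmax;
  double lo = 0.0, hi = cmax;
  while (hi - lo > 1e-6) {
    double mid = 0.5 * (lo + hi);
    if (sksq_expect(mid, thetahat) > sksq) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// core engine: statistics for the rows idx (0-based) of X
void stats_engine(const IntegerMatrix &X, const std::vector<int> &idx,
                  double cmax, double *out) {
  const int k = (int)idx.size();
  const int Sfull = X.ncol();
  const int words = (k + 63) / 64;

  std::vector<Bits> col;  // segregating columns as subset bitmasks
  std::vector<int> colcnt;
  col.reserve(Sfull);
  for (int j = 0; j < Sfull; ++j) {
    Bits m(words, 0);
    int c = 0;
    for (int i = 0; i < k; ++i) {
      if (X(idx[i], j)) { m[i >> 6] |= (uint64_t)1 << (i & 63); ++c; }
    }
    if (c > 0 && c < k) { col.push_back(m); colcnt.push_back(c); }
  }
  const int S = (int)col.size();
  Bits full(words, 0);
  for (int i = 0; i < k; ++i) full[i >> 6] |= (uint64_t)1 << (i & 63);

  // row signatures over segregating columns
  const int rwords = (S + 63) / 64;
  std::vector<Bits> row(k, Bits(std::max(rwords, 1), 0));
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < k; ++i)
      if (col[j][i >> 6] & ((uint64_t)1 << (i & 63)))
        row[i][j >> 6] |= (uint64_t)1 << (j & 63);

  // haplotype counts and diversity
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&row](int a, int b) { return row[a] < row[b]; });
  int nhaps = 0;
  double sump2 = 0.0;
  int run = 0;
  for (int i = 0; i < k; ++i) {
    ++run;
    if (i == k - 1 || row[ord[i]] != row[ord[i + 1]]) {
      ++nhaps;
      double p = (double)run / k;
      sump2 += p * p;
      run = 0;
    }
  }
  double hapdiv = (k > 1) ? ((double)k / (k - 1)) * (1.0 - sump2) : NA_REAL;
  if (!ISNA(hapdiv)) hapdiv = std::min(1.0, std::max(0.0, hapdiv));

  // pairwise sequence differences -> Hudson's C
  double kbar = 0.0, ss = 0.0;
  long npairs = (long)k * (k - 1) / 2;
  {
    std::vector<double> d;
    d.reserve(npairs);
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j) {
        int h = 0;
        for (int w = 0; w < rwords; ++w) h += popcount64(row[i][w] ^ row[j][w]);
        d.push_back((double)h);
      }
    for (size_t q = 0; q < d.size(); ++q) kbar += d[q];
    kbar /= npairs;
    for (size_t q = 0; q < d.size(); ++q) ss += (d[q] - kbar) * (d[q] - kbar);
  }
  double hudc;
  if (S == 0) hudc = 0.0;
  else if (npairs < 2) hudc = NA_REAL;
  else hudc = hudsons_c_solve(kbar, ss / (npairs - 1), cmax);

  // site-pair scan: four-gamete incompatibilities (Rmin) and ZnS
  double sum_r2 = 0.0;
  std::vector<std::pair<int, int> > incompat;
  for (int i = 0; i < S; ++i) {
    double pi = (double)colcnt[i] / k;
    for (int j = i + 1; j < S; ++j) {
      int n11 = popcount_and(col[i], col[j]);
      int n10 = colcnt[i] - n11;
      int n01 = colcnt[j] - n11;
      int n00 = k - colcnt[i] - colcnt[j] + n11;
      if (n11 > 0 && n10 > 0 && n01 > 0 && n00 > 0)
        incompat.push_back(std::make_pair(i, j));
      double pj = (double)colcnt[j] / k;
      double D = (double)n11 / k - pi * pj;
      double r2 = D * D / (pi * (1.0 - pi) * pj * (1.0 - pj));
      sum_r2 += std::min(1.0, r2); // guard rounding above the r^2 = 1 bound
    }
  }
  double zns = (S >= 2) ? sum_r2 / ((double)S * (S - 1) / 2.0) : NA_REAL;

  // Hudson-Kaplan: maximum number of disjoint open incompatibility intervals
  std::sort(incompat.begin(), incompat.end(),
            [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
              return a.second < b.second;
            });
  int rmin = 0, cur = -1;
  for (size_t q = 0; q < incompat.size(); ++q) {
    if (incompat[q].first >= cur) { ++rmin; cur = incompat[q].second; }
  }

  // Wall's B and Q over adjacent segregating-site pairs
  int bprime = 0;
  std::set<Bits> parts;
  for (int i = 0; i + 1 < S; ++i) {
    int n11 = popcount_and(col[i], col[i + 1]);
    int n10 = colcnt[i] - n11;
    int n01 = colcnt[i + 1] - n11;
    int n00 = k - colcnt[i] - colcnt[i + 1] + n11;
    bool congruent = (n10 == 0 && n01 == 0) || (n11 == 0 && n00 == 0);
    if (congruent) {
      ++bprime;
      Bits canon = col[i];
      if (canon[0] & 1) // complement so that row 0 carries 0
        for (int w = 0; w < words; ++w) canon[w] = full[w] & ~canon[w];
      parts.insert(canon);
    }
  }
  double wallb = (S >= 2) ? (double)bprime / (S - 1) : NA_REAL;
  double wallq = (S >= 1) ? ((double)bprime + (double)parts.size()) / S : NA_REAL;

  double rmmg = std::max(0.0, (double)nhaps - S - 1.0);

  out[0] = (double)S;
  out[1] = (double)rmin;
  out[2] = rmmg;
  out[3] = (double)nhaps;
  out[4] = hapdiv;
  out[5] = wallb;
  out[6] = wallq;
  out[7] = hudc;
  out[8] = zns;
}

const char *STAT_NAMES[9] = {"S", "Rmin", "rmmg", "nHaps", "HapDiv",
                             "WallB", "WallQ", "HudsonC", "ZnS"};

} // namespace

// [[Rcpp::export]]
NumericVector summary_stats_cpp(IntegerMatrix X, IntegerVector rows,
                                double cmax) {
  std::vector<int> idx(rows.size());
  for (int i = 0; i < rows.size(); ++i) {
    idx[i] = rows[i] - 1;
    if (idx[i] < 0 || idx[i] >= X.nrow()) stop("row index out of range");
  }
  if (idx.size() < 2) stop("at least two rows are required");
  NumericVector out(9);
  stats_engine(X, idx, cmax, REAL(out));
  out.attr("names") = CharacterVector(STAT_NAMES, STAT_NAMES + 9);
  return out;
}

// [[Rcpp::export]]
NumericMatrix subsample_stats_cpp(IntegerMatrix X, int tuple_n, int n_sub,
                                  double cmax, bool scale_multiply) {
  const int n = X.nrow();
  if (tuple_n < 2 || tuple_n > n) stop("tuple size out of range");
  NumericMatrix out(n_sub, 17);
  std::vector<int> pool(n);
  double st[9];
  for (int b = 0; b < n_sub; ++b) {
    for (int i = 0; i < n; ++i) pool[i] = i;
    for (int t = 0; t < tuple_n; ++t) { // partial Fisher-Yates
      int r = t + (int)(unif_rand() * (n - t));
      if (r >= n) r = n - 1;
      std::swap(pool[t], pool[r]);
    }
    std::vector<int> idx(pool.begin(), pool.begin() + tuple_n);
    stats_engine(X, idx, cmax, st);
    for (int q = 0; q < 9; ++q) out(b, q) = st[q];
    double S = st[0];
    for (int q = 1; q < 9; ++q) {
      double v = st[q];
      if (S <= 0.0 || ISNA(v)) out(b, 8 + q) = NA_REAL;
      else out(b, 8 + q) = scale_multiply ? v * S : v / S;
    }
  }
  CharacterVector nm(17);
  for (int q = 0; q < 9; ++q) nm[q] = STAT_NAMES[q];
  for (int q = 1; q < 9; ++q)
    nm[8 + q] = std::string(STAT_NAMES[q]) + "_scaled";
  colnames(out) = nm;
  return out;
}

// [[Rcpp::export]]
double hudsons_c_cpp(double thetahat, double sksq, double cmax) {
  return hudsons_c_solve(thetahat, sksq, cmax);
}

// [[Rcpp::export]]
double sksq_expect_cpp(double C, double thetahat) {
  return sksq_expect(C, thetahat);
}
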