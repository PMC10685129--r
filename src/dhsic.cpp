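#include <Rcpp.h>
using namespace Rcpp;

// Null-distribution workhorses. Both exploit that circularly shifting or
// permuting a variable's samples only relabels rows/columns of its Gram
// matrix: term 1 is re-evaluated with remapped indices, term 2 reuses the
// precomputed row sums (a relabelling permutes them), and term 3 is
// invariant, so each resampled statistic costs O(d m^2) with no kernel
// re-evaluation.

// Relabelled three-term statistic. idx[j] maps the common sample index to
// variable j's row/column (identity for the fixed first variable).
static double stat_relabel(const std::vector<const double *> &K,
                           const std::vector<const double *> &rowsum,
                           const std::vector<const int *> &idx,
                           const int m, const int d, const double term3) {
  long double t1 = 0.0L;
  std::vector<const double *> col(d);
  for (int b = 0; b < m; ++b) {
    for (int j = 0; j < d; ++j) col[j] = K[j] + (size_t)idx[j][b] * m;
    double s = 0.0;
    if (d == 2) {
      const double *c0 = col[0], *c1 = col[1];
      const int *i1 = idx[1];
      for (int a = 0; a < m; ++a) s += c0[idx[0][a]] * c1[i1[a]];
    } else if (d == 3) {
      const double *c0 = col[0], *c1 = col[1], *c2 = col[2];
      const int *i0 = idx[0], *i1 = idx[1], *i2 = idx[2];
      for (int a = 0; a < m; ++a) s += c0[i0[a]] * c1[i1[a]] * c2[i2[a]];
    } else {
      for (int a = 0; a < m; ++a) {
        double p = 1.0;
        for (int j = 0; j < d; ++j) p *= col[j][idx[j][a]];
        s += p;
      }
    }
    t1 += s;
  }
  long double t2 = 0.0L;
  const double dm = (double)m;
  for (int a = 0; a < m; ++a) {
    double p = 1.0;
    for (int j = 0; j < d; ++j) p *= rowsum[j][idx[j][a]] / dm;
    t2 += p;
  }
  return (double)(t1 / ((long double)m * m) - 2.0L * t2 / m) + term3;
}

static void precompute(const List &grams, std::vector<const double *> &K,
                       std::vector<NumericVector> &rs,
                       std::vector<const double *> &rowsum, int &m, int &d,
                       double &term3) {
  d = grams.size();
  NumericMatrix g0 = grams[0];
  m = g0.nrow();
  K.resize(d);
  rs.resize(d);
  rowsum.resize(d);
  term3 = 1.0;
  for (int j = 0; j < d; ++j) {
    NumericMatrix g = grams[j];
    if (g.nrow() != m || g.ncol() != m)
      stop("Gram matrices must be square and of identical size");
    K[j] = REAL(g);
    NumericVector r(m);
    long double tot = 0.0L;
    for (int a = 0; a < m; ++a) {
      long double s = 0.0L;
      for (int b = 0; b < m; ++b) s += K[j][a + (size_t)b * m];
      r[a] = (double)s;
      tot += s;
    }
    rs[j] = r;
    rowsum[j] = REAL(rs[j]);
    term3 *= (double)(tot / ((long double)m * m));
  }
}

// [[Rcpp::export]]
NumericVector shift_null_stats(List grams, IntegerMatrix taus) {
  std::vector<const double *> K, rowsum;
  std::vector<NumericVector> rs;
  int m, d;
  double term3;
  precompute(grams, K, rs, rowsum, m, d, term3);
  const int S = taus.nrow();
  if (taus.ncol() != d - 1) stop("taus must have d - 1 columns");
  NumericVector out(S);
  std::vector<std::vector<int>> maps(d);
  std::vector<const int *> idx(d);
  for (int j = 0; j < d; ++j) maps[j].resize(m);
  for (int a = 0; a < m; ++a) maps[0][a] = a; // variable 1 fixed
  idx[0] = maps[0].data();
  for (int s = 0; s < S; ++s) {
    for (int j = 1; j < d; ++j) {
      const int tau = ((taus(s, j - 1) % m) + m) % m;
      for (int a = 0; a < m; ++a) maps[j][a] = (a + tau) % m;
      idx[j] = maps[j].data();
    }
    out[s] = stat_relabel(K, rowsum, idx, m, d, term3);
  }
  return out;
}

// perms: list of length P; element p is an IntegerMatrix m x (d-1) of
// 0-based realization indices for variables 2..d.
// [[Rcpp::export]]
NumericVector perm_null_stats(List grams, List perms) {
  std::vector<const double *> K, rowsum;
  std::vector<NumericVector> rs;
  int m, d;
  double term3;
  precompute(grams, K, rs, rowsum, m, d, term3);
  const int P = perms.size();
  NumericVector out(P);
  std::vector<int> ident(m);
  for (int a = 0; a < m; ++a) ident[a] = a;
  std::vector<const int *> idx(d);
  idx[0] = ident.data();
  for (int p = 0; p < P; ++p) {
    IntegerMatrix pm = perms[p];
    if (pm.nrow() != m || pm.ncol() != d - 1)
      stop("each permutation matrix must be m x (d - 1)");
    const int *base = INTEGER(pm);
    for (int j = 1; j < d; ++j) idx[j] = base + (size_t)(j - 1) * m;
    out[p] = stat_relabel(K, rowsum, idx, m, d, term3);
  }
  return out;
}
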