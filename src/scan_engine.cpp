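// Per-marker partial-F scan kernel and permutation loop.
//
// The marker enters as a categorical factor (B6/B6 reference, up to 2 df);
// for every marker we fit the covariate-only and covariate+marker least-
// squares models on that marker's complete cases and return the residual
// sums of squares plus the genotype-class coefficients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Column layout of the per-marker result row.
enum { COL_N = 0, COL_NCLASS, COL_DFNUM, COL_RSS0, COL_RSS1,
       COL_EFF_HET, COL_EFF_FVB, NCOL_OUT };

// Fit one marker on the complete-case subset `use` (row indices into X/y).
// g holds genotype codes 0 (B6/B6), 1 (het), 2 (FVB/FVB) for those rows.
static void fit_marker(const arma::mat& X, const arma::vec& y,
                       const std::vector<arma::uword>& use,
                       const std::vector<int>& g, double* out) {
  const arma::uword nu = use.size();
  const arma::uword p = X.n_cols;
  int nb = 0, nh = 0, nf = 0;
  for (int gi : g) { if (gi == 0) ++nb; else if (gi == 1) ++nh; else ++nf; }
  const int ncls = (nb > 0) + (nh > 0) + (nf > 0);
  out[COL_N] = (double)nu;
  out[COL_NCLASS] = (double)ncls;
  if (ncls < 2 || nu < p + (arma::uword)ncls + 1) return;

  const int dfn = ncls - 1;
  out[COL_DFNUM] = (double)dfn;

  arma::mat W(nu, p + dfn, arma::fill::zeros);
  arma::vec ys(nu);
  // dummy columns (het indicator, FVB/FVB indicator) relative to the first
  // genotype class present; that is B6/B6 whenever it is observed
  int col_het = -1, col_fvb = -1, next = p;
  const int ref = (nb > 0) ? 0 : ((nh > 0) ? 1 : 2);
  if (nh > 0 && ref != 1) col_het = next++;
  if (nf > 0 && ref != 2) col_fvb = next++;

  for (arma::uword j = 0; j < nu; ++j) {
    W.row(j).cols(0, p - 1) = X.row(use[j]);
    ys[j] = y[use[j]];
    if (g[j] == 1 && col_het >= 0) W(j, col_het) = 1.0;
    if (g[j] == 2 && col_fvb >= 0) W(j, col_fvb) = 1.0;
  }

  const arma::mat X0 = W.cols(0, p - 1);
  arma::vec b0, b1;
  bool ok0 = arma::solve(b0, X0, ys, arma::solve_opts::no_approx);
  bool ok1 = arma::solve(b1, W, ys, arma::solve_opts::no_approx);
  if (!ok0 || !ok1) { out[COL_DFNUM] = NA_REAL; return; }
  arma::vec r0 = ys - X0 * b0;
  arma::vec r1 = ys - W * b1;
  out[COL_RSS0] = arma::dot(r0, r0);
  out[COL_RSS1] = arma::dot(r1, r1);
  // effects relative to B6/B6 are only defined when B6/B6 is the reference
  if (ref == 0) {
    if (col_het >= 0) out[COL_EFF_HET] = b1[col_het];
    if (col_fvb >= 0) out[COL_EFF_FVB] = b1[col_fvb];
  }
}

// [[Rcpp::export(name = ".scan_engine")]]
NumericMatrix scan_engine(const arma::mat& X, const arma::vec& y,
                          const IntegerMatrix& G) {
  const int n = X.n_rows, M = G.ncol();
  NumericMatrix out(M, NCOL_OUT);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<arma::uword> use; std::vector<int> g;
  double row[NCOL_OUT];
  for (int m = 0; m < M; ++m) {
    use.clear(); g.clear();
    for (int i = 0; i < n; ++i) {
      const int gi = G(i, m);
      if (gi != NA_INTEGER) { use.push_back(i); g.push_back(gi); }
    }
    std::fill(row, row + NCOL_OUT, NA_REAL);
    fit_marker(X, y, use, g, row);
    for (int j = 0; j < NCOL_OUT; ++j) out(m, j) = row[j];
  }
  colnames(out) = CharacterVector::create("n", "nclass", "df_num",
                                          "rss0", "rss1",
                                          "effect_het", "effect_fvb");
  return out;
}

// Genome-wide maximum of -log10 p over markers for each permutation.
// perms is an n x n_perm matrix of 1-based row permutations applied to the
// genotype matrix (covariate/phenotype pairs stay intact).
// [[Rcpp::export(name = ".perm_max_stat")]]
NumericVector perm_max_stat(const arma::mat& X, const arma::vec& y,
                            const IntegerMatrix& G,
                            const IntegerMatrix& perms) {
  const int n = X.n_rows, M = G.ncol(), K = perms.ncol();
  const arma::uword p = X.n_cols;
  NumericVector mx(K, NA_REAL);
  std::vector<arma::uword> use; std::vector<int> g;
  double row[NCOL_OUT];
  for (int k = 0; k < K; ++k) {
    double best = R_NegInf;
    for (int m = 0; m < M; ++m) {
      use.clear(); g.clear();
      for (int i = 0; i < n; ++i) {
        const int gi = G(perms(i, k) - 1, m);
        if (gi != NA_INTEGER) { use.push_back(i); g.push_back(gi); }
      }
      std::fill(row, row + NCOL_OUT, NA_REAL);
      fit_marker(X, y, use, g, row);
      if (!R_finite(row[COL_RSS1]) || row[COL_RSS1] <= 0) continue;
      const double dfn = row[COL_DFNUM];
      const double dfd = row[COL_N] - (double)p - dfn;
      if (dfd <= 0) continue;
      const double f = ((row[COL_RSS0] - row[COL_RSS1]) / dfn) /
                       (row[COL_RSS1] / dfd);
      const double lod = -R::pf(f, dfn, dfd, 0, 1) / M_LN10;
      if (lod > best) best = lod;
    }
    mx[k] = best;
    if (k % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return mx;
}
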