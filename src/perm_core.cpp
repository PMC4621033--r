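// Permutation null of the weighted Fisher statistic.
//
// Each permutation redraws the gene-set allocation (gs_size genes sampled
// from the PDR universe without replacement), recomputes the Kendall tau-b
// concordance matrix and PCA study weights on that random set, draws
// per-study p-values from U(0,1) and evaluates M = -2 sum w_s log p_s.
// Uses R's RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// tie-corrected Kendall tau-b; returns 0 when a vector is constant
// (no rank information)
static double kendall_tau_b(const double* x, const double* y, int n) {
  double num = 0.0, tx = 0.0, ty = 0.0;
  const double n0 = 0.5 * n * (n - 1);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx == 0.0 && dy == 0.0) { tx += 1.0; ty += 1.0; }
      else if (dx == 0.0) tx += 1.0;
      else if (dy == 0.0) ty += 1.0;
      else num += ((dx > 0.0) == (dy > 0.0)) ? 1.0 : -1.0;
    }
  }
  const double den = std::sqrt((n0 - tx) * (n0 - ty));
  if (den <= 0.0) return 0.0;
  return num / den;
}

// exported for cross-checking against stats::cor(method = "kendall")
// [[Rcpp::export]]
double kendall_tau_b_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  if (x.size() != y.size()) Rcpp::stop("length mismatch");
  return kendall_tau_b(x.begin(), y.begin(), x.size());
}

// [[Rcpp::export]]
Rcpp::NumericVector perm_null_stats(const arma::mat& universe, int gs_size,
                                    int n_perm) {
  const int n_genes = universe.n_rows, n_s = universe.n_cols;
  if (gs_size < 2 || gs_size > n_genes)
    Rcpp::stop("gs_size must lie in [2, n_genes]");
  if (n_s < 2) Rcpp::stop("need at least two studies");
  Rcpp::NumericVector out(n_perm);
  std::vector<int> idx(n_genes);
  arma::mat sub(gs_size, n_s), tau(n_s, n_s), evec;
  arma::vec eval;
  Rcpp::RNGScope scope;
  for (int j = 0; j < n_perm; ++j) {
    // partial Fisher-Yates draw of gs_size distinct gene rows
    for (int i = 0; i < n_genes; ++i) idx[i] = i;
    for (int i = 0; i < gs_size; ++i) {
      int k = i + (int)(unif_rand() * (n_genes - i));
      if (k >= n_genes) k = n_genes - 1;
      std::swap(idx[i], idx[k]);
    }
    for (int i = 0; i < gs_size; ++i) sub.row(i) = universe.row(idx[i]);
    tau.eye();
    for (int a = 0; a < n_s; ++a)
      for (int b = a + 1; b < n_s; ++b) {
        const double t = kendall_tau_b(sub.colptr(a), sub.colptr(b),
                                       gs_size);
        tau(a, b) = t;
        tau(b, a) = t;
      }
    arma::eig_sym(eval, evec, tau);          // ascending eigenvalues
    const double ev1 = eval(n_s - 1);
    arma::vec pc1 = evec.col(n_s - 1);
    if (arma::accu(pc1) < 0.0) pc1 = -pc1;
    const double s = arma::accu(arma::abs(pc1));  // never 0 for a unit vector
    double m = 0.0;
    for (int a = 0; a < n_s; ++a) {
      const double w = pc1(a) / s * ev1 / n_s;
      double p = unif_rand();
      if (p <= 0.0) p = DBL_MIN;
      m += -2.0 * w * std::log(p);
    }
    out[j] = m;
  }
  return out;
}
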