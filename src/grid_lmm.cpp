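// Grid-profile maximum-likelihood scans for the single-locus linear mixed
// model. Inputs arrive pre-rotated by the eigenvectors of the kinship
// matrix, so the model's covariance is diagonal: D = h2 * lambda + (1 - h2).
// For each grid value of h2 the GLS residual sum of squares of the null
// design and of every marker design is computed for every response column
// (column 1 = observed phenotype, further columns = permuted copies), and
// the profiled ML log-likelihood is maximized over the grid.

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List grid_lmm_scan(const arma::mat& Y, const arma::mat& X0, const List& Xm,
                   const arma::vec& lambda, const arma::vec& grid) {
  const arma::uword n = Y.n_rows, q = Y.n_cols, G = grid.n_elem;
  const arma::uword nm = Xm.size(), p0 = X0.n_cols;

  arma::mat ll0(G, q), rss0(G, q);
  arma::mat ll_alt(nm, q);  ll_alt.fill(-arma::datum::inf);
  arma::umat gbest(nm, q, arma::fill::zeros);
  arma::mat rss_alt(nm, q, arma::fill::zeros);
  arma::ivec df(nm);
  LogicalVector ok(nm, true);

  std::vector<arma::mat> X(nm);
  for (arma::uword j = 0; j < nm; j++) {
    arma::mat xj = as<arma::mat>(Xm[j]);
    X[j] = arma::join_rows(X0, xj);
    df[j] = xj.n_cols;
    // weights are strictly positive, so rank(X' W X) = rank(X) for every
    // grid point; collinear designs are skipped once here
    if (arma::rank(X[j]) < X[j].n_cols) ok[j] = false;
  }

  for (arma::uword g = 0; g < G; g++) {
    arma::vec D = grid[g] * lambda + (1.0 - grid[g]);
    arma::vec w = 1.0 / D;
    double logdet = arma::sum(arma::log(D));
    arma::mat Yw = Y.each_col() % w;
    arma::rowvec yWy = arma::sum(Y % Yw, 0);

    arma::mat X0w = X0.each_col() % w;
    arma::mat A0i;
    if (!arma::inv_sympd(A0i, X0.t() * X0w))
      stop("null design is singular");
    arma::mat B0 = X0w.t() * Y;
    for (arma::uword c = 0; c < q; c++) {
      double rss = yWy[c] - arma::as_scalar(B0.col(c).t() * A0i * B0.col(c));
      if (rss < 1e-300) rss = 1e-300;
      rss0(g, c) = rss;
      ll0(g, c) = -0.5 * (n * std::log(2.0 * M_PI * rss / n) + n + logdet);
    }

    for (arma::uword j = 0; j < nm; j++) {
      if (!ok[j]) continue;
      arma::mat Xw = X[j].each_col() % w;
      arma::mat Ai;
      if (!arma::inv_sympd(Ai, X[j].t() * Xw)) continue;
      arma::mat B = Xw.t() * Y;
      for (arma::uword c = 0; c < q; c++) {
        double rss = yWy[c] - arma::as_scalar(B.col(c).t() * Ai * B.col(c));
        if (rss < 1e-300) rss = 1e-300;
        double ll = -0.5 * (n * std::log(2.0 * M_PI * rss / n) + n + logdet);
        if (ll > ll_alt(j, c)) {
          ll_alt(j, c) = ll;
          gbest(j, c) = g + 1;
          rss_alt(j, c) = rss;
        }
      }
    }
  }

  for (arma::uword j = 0; j < nm; j++)
    if (ok[j] && gbest(j, 0) == 0) ok[j] = false;

  return List::create(_["ll0"] = ll0, _["rss0"] = rss0,
                      _["ll_alt"] = ll_alt, _["gbest"] = gbest,
                      _["rss_alt"] = rss_alt, _["df"] = df, _["ok"] = ok);
}
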