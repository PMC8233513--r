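#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-pattern log-likelihood by Felsenstein pruning under a reversible
// substitution process with a finite rate mixture (discrete gamma).
//
// The rate matrix is supplied through the eigendecomposition of its
// pi-symmetrized form: with D = diag(sqrt(pi)),  B = D Q D^{-1} = V L V',
// so  P(t) = D^{-1} V exp(L t) V' D.
//
// edge:          nedge x 2 integer matrix (parent, child), 1-based node ids,
//                rows in postorder (every child row precedes its parent's row)
// elen:          branch lengths, expected substitutions per site
// eigvals, V:    eigendecomposition of the symmetrized rate matrix
// pi:            stationary frequencies
// tip_partials:  cube nstates x npatterns x ntips; tip i occupies slice i
// rates,weights: mixture category rates and probabilities (sum to 1)
// nnode:         total number of nodes (tips + internal)
// root:          1-based id of the root node
//
// Returns a vector of per-pattern mixture log-likelihoods.  Partial
// likelihoods are rescaled per pattern only when they drift below 1e-100,
// which keeps the common case to two passes per branch.
// [[Rcpp::export]]
arma::vec cpp_mixture_loglik(const arma::imat& edge,
                             const arma::vec& elen,
                             const arma::vec& eigvals,
                             const arma::mat& V,
                             const arma::vec& pi,
                             const arma::cube& tip_partials,
                             const arma::vec& rates,
                             const arma::vec& weights,
                             const int nnode,
                             const int root) {
  const arma::uword ns = pi.n_elem;
  const arma::uword npat = tip_partials.n_cols;
  const arma::uword ntip = tip_partials.n_slices;
  const arma::uword nedge = edge.n_rows;
  const arma::uword K = rates.n_elem;

  arma::vec sqp = arma::sqrt(pi);
  // P(t) = Lm * diag(exp(eigvals * t)) * Rm
  arma::mat Lm = V.each_col() / sqp;
  arma::mat Rm = V.t();
  Rm.each_row() %= sqp.t();

  arma::mat logmix(npat, K, arma::fill::zeros);
  arma::cube down(ns, npat, nnode);
  arma::mat m(ns, npat);
  arma::mat P(ns, ns);

  for (arma::uword k = 0; k < K; ++k) {
    arma::rowvec logscale(npat, arma::fill::zeros);
    for (arma::uword i = 0; i < ntip; ++i)
      down.slice(i) = tip_partials.slice(i);
    down.tail_slices(nnode - ntip).ones();

    for (arma::uword e = 0; e < nedge; ++e) {
      const int p = edge(e, 0) - 1;
      const int c = edge(e, 1) - 1;
      const double t = elen(e) * rates(k);
      arma::vec ev = arma::exp(eigvals * t);
      P = (Lm.each_row() % ev.t()) * Rm;
      // spectral reconstruction can leave tiny negative probabilities
      P.clamp(0.0, arma::datum::inf);
      m = P * down.slice(c);
      arma::mat& dp = down.slice(p);
      dp %= m;
      if (dp.min() < 1e-100) {
        arma::rowvec mx = arma::max(dp, 0);
        mx.clamp(1e-300, arma::datum::inf);
        dp.each_row() /= mx;
        logscale += arma::log(mx);
      }
    }
    arma::rowvec lik = pi.t() * down.slice(root - 1);
    lik.clamp(1e-300, arma::datum::inf);
    logmix.col(k) = (arma::log(lik) + logscale).t();
  }

  // log-sum-exp over mixture categories
  arma::vec out(npat);
  arma::vec lw = arma::log(weights);
  for (arma::uword s = 0; s < npat; ++s) {
    arma::rowvec z = logmix.row(s) + lw.t();
    double mz = z.max();
    out(s) = mz + std::log(arma::accu(arma::exp(z - mz)));
  }
  return out;
}
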