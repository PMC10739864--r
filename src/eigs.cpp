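// Sparse non-symmetric eigensolver for the edge-space operators (Hashimoto B,
// flow F). ARPACK-style iteration via Armadillo's eigs_gen; the random start
// vector draws from R's RNG, so callers seed with set.seed() for
// reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List eigs_lr_sparse(const arma::sp_mat& X, int k, int maxiter, int subdim) {
  arma::cx_vec eigval;
  arma::cx_mat eigvec;
  arma::eigs_opts opts;
  opts.maxiter = maxiter;
  if (subdim > 0) opts.subdim = subdim;

  bool ok = arma::eigs_gen(eigval, eigvec, X, k, "lr", opts);
  if (!ok || eigval.n_elem == 0)
    stop("sparse eigensolver failed to converge (n = %d, k = %d, maxiter = %d)",
         (int) X.n_rows, k, maxiter);

  return List::create(_["values"] = eigval, _["vectors"] = eigvec,
                      _["nconv"] = (int) eigval.n_elem);
}
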