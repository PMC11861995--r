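// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Multiply a block-diagonal operator made of per-graph adjacency slices with a
// row-stacked node matrix: out[rows of graph g] = A[,,idx[g]] %*% H[rows of g].
// All graphs share the same node count n; H has length(idx) * n rows.
// [[Rcpp::export]]
arma::mat block_adj_multiply(const arma::cube& A, const arma::mat& H,
                             const arma::uvec& idx) {
  const arma::uword n = A.n_rows;
  const arma::uword B = idx.n_elem;
  if (H.n_rows != B * n) {
    Rcpp::stop("H has %d rows; expected %d (= %d graphs x %d nodes)",
               (int)H.n_rows, (int)(B * n), (int)B, (int)n);
  }
  arma::mat out(H.n_rows, H.n_cols);
  for (arma::uword g = 0; g < B; ++g) {
    const arma::uword r0 = g * n;
    out.rows(r0, r0 + n - 1) = A.slice(idx[g] - 1) * H.rows(r0, r0 + n - 1);
  }
  return out;
}
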