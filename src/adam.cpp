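#include <Rcpp.h>

// Fused in-place Adam step with L2 weight decay over flattened parameter
// leaves. params/m/v are mutated in place; the caller owns these arrays and
// guarantees they are not aliased elsewhere (train_deep deep-copies the
// parameter tree before training and when snapshotting best weights).
// [[Rcpp::export]]
void adam_update_inplace(Rcpp::List params, Rcpp::List grads, Rcpp::List m,
                         Rcpp::List v, double lr, double wd, int t,
                         double beta1, double beta2, double eps) {
  const double inv_bc1 = 1.0 / (1.0 - std::pow(beta1, t));
  const double inv_sqrt_bc2 = 1.0 / std::sqrt(1.0 - std::pow(beta2, t));
  const double om1 = 1.0 - beta1, om2 = 1.0 - beta2;
  const double step = lr * inv_bc1;
  for (int i = 0; i < params.size(); ++i) {
    Rcpp::NumericVector p = params[i], g = grads[i], mm = m[i], vv = v[i];
    const R_xlen_t len = p.size();
    if (g.size() != len || mm.size() != len || vv.size() != len) {
      Rcpp::stop("parameter/gradient shape mismatch in leaf %d", i + 1);
    }
    double *pp = p.begin(), *mp = mm.begin(), *vp = vv.begin();
    const double *gp = g.begin();
    for (R_xlen_t j = 0; j < len; ++j) {
      const double gj = gp[j] + wd * pp[j];
      mp[j] = beta1 * mp[j] + om1 * gj;
      vp[j] = beta2 * vp[j] + om2 * gj * gj;
      pp[j] -= step * mp[j] / (std::sqrt(vp[j]) * inv_sqrt_bc2 + eps);
    }
  }
}
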