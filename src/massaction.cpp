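#include <Rcpp.h>
using namespace Rcpp;

// Mass-action derivative for a list of uni/bimolecular reactions.
// r1,r2 / p1,p2 hold 1-based species indices (0 = absent second participant).
// Returns dy/dt with every reaction's net flux applied to its participants.
// [[Rcpp::export(name = ".massaction_deriv")]]
NumericVector massaction_deriv(NumericVector y,
                               IntegerVector r1, IntegerVector r2,
                               IntegerVector p1, IntegerVector p2,
                               NumericVector kf, NumericVector kr) {
  const int ns = y.size(), nr = r1.size();
  NumericVector dy(ns);
  for (int i = 0; i < nr; ++i) {
    double fwd = kf[i] * y[r1[i] - 1];
    if (r2[i] > 0) fwd *= y[r2[i] - 1];
    double rev = 0.0;
    if (kr[i] > 0.0) {
      rev = kr[i] * y[p1[i] - 1];
      if (p2[i] > 0) rev *= y[p2[i] - 1];
    }
    const double net = fwd - rev;
    dy[r1[i] - 1] -= net;
    if (r2[i] > 0) dy[r2[i] - 1] -= net;
    dy[p1[i] - 1] += net;
    if (p2[i] > 0) dy[p2[i] - 1] += net;
  }
  return dy;
}
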