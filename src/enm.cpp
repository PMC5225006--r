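#include <Rcpp.h>
using namespace Rcpp;

// Dense anisotropic-network Hessian. pairs: m x 2 (1-based contact list);
// off-diagonal 3x3 block for pair (i,j) is -gamma * d d^T with d the unit
// inter-node vector; diagonal blocks accumulate the negated sum.
// [[Rcpp::export]]
NumericMatrix hessian_kernel(NumericMatrix coords, IntegerMatrix pairs,
                             double gamma) {
  const int n = coords.nrow();
  NumericMatrix H(3 * n, 3 * n);
  for (int k = 0; k < pairs.nrow(); ++k) {
    const int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double d[3] = {coords(j, 0) - coords(i, 0),
                   coords(j, 1) - coords(i, 1),
                   coords(j, 2) - coords(i, 2)};
    const double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    for (int a = 0; a < 3; ++a) d[a] /= nrm;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        const double blk = gamma * d[a] * d[b];
        H(3 * i + a, 3 * j + b) -= blk;
        H(3 * j + a, 3 * i + b) -= blk;
        H(3 * i + a, 3 * i + b) += blk;
        H(3 * j + a, 3 * j + b) += blk;
      }
  }
  return H;
}
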