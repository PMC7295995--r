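// In-place SGD-with-momentum update: V <- mom * V - lr * G; W <- W + V.
// W and V are owned exclusively by the training loop, which creates them
// immediately before use; mutating them in place avoids copying the large
// fully-connected weight matrices every mini-batch.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".sgd_step_cpp")]]
void sgd_step_cpp(NumericVector W, NumericVector V, const NumericVector& G,
                  double momentum, double lr) {
  const R_xlen_t n = W.size();
  if (V.size() != n || G.size() != n) stop("shape mismatch in SGD update");
  double* w = REAL(W);
  double* v = REAL(V);
  const double* g = REAL(G);
  for (R_xlen_t i = 0; i < n; ++i) {
    v[i] = momentum * v[i] - lr * g[i];
    w[i] += v[i];
  }
}
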