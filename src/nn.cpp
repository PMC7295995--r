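// Batch forward/backward passes of the 1D convolutional velocity classifier.
// Layout conventions match the R reference implementation in R/network.R:
// records are rows, conv output rows are indexed (b, p) with b fastest,
// flattened features are (pool position, kernel) with position fastest.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col gather: X is B x input_len, returns (B*conv_out) x klen
static mat im2col(const mat& X, int klen, int conv_out) {
  const int B = X.n_rows;
  mat M(B * conv_out, klen);
  for (int w = 0; w < klen; ++w)
    for (int p = 0; p < conv_out; ++p)
      M(span(p * B, p * B + B - 1), span(w, w)) = X.col(p + w);
  return M;
}

struct Forward {
  mat M, A, P, F, H1, H2, probs;
  umat Pidx;  // conv-output position (0-based p) feeding each pooled value
};

static Forward forward_pass(const mat& X, const mat& Wc, const vec& bc,
                            const mat& W1, const vec& b1,
                            const mat& W2, const vec& b2,
                            const mat& W3, const vec& b3,
                            int pool_len, int pool_stride) {
  Forward fw;
  const int B = X.n_rows;
  const int klen = Wc.n_rows;
  const int K = Wc.n_cols;
  const int conv_out = X.n_cols - klen + 1;
  const int pool_out = (conv_out - pool_len) / pool_stride + 1;

  fw.M = im2col(X, klen, conv_out);
  fw.A = fw.M * Wc;
  fw.A.each_row() += bc.t();
  fw.A.transform([](double v) { return v > 0.0 ? v : 0.0; });

  fw.P.set_size(B * pool_out, K);
  fw.Pidx.set_size(B * pool_out, K);
  for (int c = 0; c < K; ++c) {
    const double* ac = fw.A.colptr(c);
    double* pc = fw.P.colptr(c);
    uword* ic = fw.Pidx.colptr(c);
    for (int k = 0; k < pool_out; ++k) {
      const int p0 = k * pool_stride;
      for (int b = 0; b < B; ++b) {
        double best = ac[b + p0 * B];
        int bestp = p0;
        for (int j = 1; j < pool_len; ++j) {
          const double v = ac[b + (p0 + j) * B];
          if (v > best) { best = v; bestp = p0 + j; }
        }
        pc[b + k * B] = best;
        ic[b + k * B] = bestp;
      }
    }
  }

  fw.F.set_size(B, pool_out * K);
  for (int c = 0; c < K; ++c)
    for (int k = 0; k < pool_out; ++k)
      fw.F.col(k + c * pool_out) = fw.P(span(k * B, k * B + B - 1), span(c, c));

  fw.H1 = fw.F * W1; fw.H1.each_row() += b1.t();
  fw.H1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  fw.H2 = fw.H1 * W2; fw.H2.each_row() += b2.t();
  fw.H2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat O = fw.H2 * W3; O.each_row() += b3.t();
  O.each_col() -= max(O, 1);
  fw.probs = exp(O);
  fw.probs.each_col() /= sum(fw.probs, 1);
  return fw;
}

// [[Rcpp::export(name = ".nn_predict_cpp")]]
arma::mat nn_predict_cpp(const arma::mat& X, const arma::mat& Wc,
                         const arma::vec& bc, const arma::mat& W1,
                         const arma::vec& b1, const arma::mat& W2,
                         const arma::vec& b2, const arma::mat& W3,
                         const arma::vec& b3, int pool_len, int pool_stride) {
  return forward_pass(X, Wc, bc, W1, b1, W2, b2, W3, b3,
                      pool_len, pool_stride).probs;
}

// Cross-entropy loss and gradients for one mini-batch. Y is one-hot.
// [[Rcpp::export(name = ".nn_batch_grad_cpp")]]
Rcpp::List nn_batch_grad_cpp(const arma::mat& X, const arma::mat& Y,
                             const arma::mat& Wc, const arma::vec& bc,
                             const arma::mat& W1, const arma::vec& b1,
                             const arma::mat& W2, const arma::vec& b2,
                             const arma::mat& W3, const arma::vec& b3,
                             int pool_len, int pool_stride) {
  const int B = X.n_rows;
  const int klen = Wc.n_rows;
  const int K = Wc.n_cols;
  const int conv_out = X.n_cols - klen + 1;
  const int pool_out = (conv_out - pool_len) / pool_stride + 1;

  Forward fw = forward_pass(X, Wc, bc, W1, b1, W2, b2, W3, b3,
                            pool_len, pool_stride);
  const double loss = -accu(Y % log(fw.probs + 1e-300)) / B;

  mat dO = (fw.probs - Y) / B;
  mat gW3 = fw.H2.t() * dO;
  vec gb3 = sum(dO, 0).t();
  mat dH2 = dO * W3.t();
  dH2.elem(find(fw.H2 <= 0)).zeros();
  mat gW2 = fw.H1.t() * dH2;
  vec gb2 = sum(dH2, 0).t();
  mat dH1 = dH2 * W2.t();
  dH1.elem(find(fw.H1 <= 0)).zeros();
  mat gW1 = fw.F.t() * dH1;
  vec gb1 = sum(dH1, 0).t();
  mat dF = dH1 * W1.t();

  // route pooled gradients back to the argmax conv position (first max);
  // positions whose max activation is zero were ReLU-clipped: no gradient
  mat dA(B * conv_out, K, fill::zeros);
  for (int c = 0; c < K; ++c) {
    double* dac = dA.colptr(c);
    const uword* ic = fw.Pidx.colptr(c);
    const double* pc = fw.P.colptr(c);
    for (int k = 0; k < pool_out; ++k)
      for (int b = 0; b < B; ++b) {
        const uword r = b + k * B;
        if (pc[r] > 0.0)
          dac[b + ic[r] * B] += dF(b, k + c * pool_out);
      }
  }
  mat gWc = fw.M.t() * dA;
  vec gbc = sum(dA, 0).t();

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("Wc") = gWc, Rcpp::Named("bc") = gbc,
    Rcpp::Named("W1") = gW1, Rcpp::Named("b1") = gb1,
    Rcpp::Named("W2") = gW2, Rcpp::Named("b2") = gb2,
    Rcpp::Named("W3") = gW3, Rcpp::Named("b3") = gb3);
}
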