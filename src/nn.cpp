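// Fast inner engine for the sigmoid feed-forward networks: forward pass,
// weighted normalized squared error, and backpropagated gradient on the
// flat parameter vector.  Layout of the flat vector matches the R side
// (pack_params): all weight matrices in layer order, column-major, then
// all bias vectors in layer order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void unflatten(const vec& w, const ivec& sizes,
                      std::vector<mat>& W, std::vector<rowvec>& b) {
  const int L = sizes.n_elem - 1; // number of connection layers
  W.resize(L);
  b.resize(L);
  uword pos = 0;
  for (int l = 0; l < L; ++l) {
    const uword r = sizes[l], c = sizes[l + 1];
    W[l] = reshape(w.subvec(pos, pos + r * c - 1), r, c);
    pos += r * c;
  }
  for (int l = 0; l < L; ++l) {
    const uword c = sizes[l + 1];
    b[l] = w.subvec(pos, pos + c - 1).t();
    pos += c;
  }
}

static mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export]]
arma::vec cpp_nn_scores(const arma::vec& w, const arma::ivec& sizes,
                        const arma::mat& X) {
  std::vector<mat> W;
  std::vector<rowvec> b;
  unflatten(w, sizes, W, b);
  mat a = X;
  for (size_t l = 0; l < W.size(); ++l) {
    a = sigm(a * W[l] + repmat(b[l], a.n_rows, 1));
  }
  return a.col(0);
}

// Weighted normalized SSE and (optionally) its exact gradient.
// sw: per-sample weights (inverse class prevalence); error is divided by
// accu(sw) so it lies in [0, 1].
// [[Rcpp::export]]
Rcpp::List cpp_nn_err_grad(const arma::vec& w, const arma::ivec& sizes,
                           const arma::mat& X, const arma::vec& y,
                           const arma::vec& sw, bool need_grad) {
  std::vector<mat> W;
  std::vector<rowvec> b;
  unflatten(w, sizes, W, b);
  const int L = W.size();
  std::vector<mat> acts(L + 1);
  acts[0] = X;
  for (int l = 0; l < L; ++l) {
    acts[l + 1] = sigm(acts[l] * W[l] + repmat(b[l], acts[l].n_rows, 1));
  }
  const vec out = acts[L].col(0);
  const double wtot = accu(sw);
  const vec resid = out - y;
  const double err = accu(sw % square(resid)) / wtot;
  if (!need_grad) {
    return Rcpp::List::create(Rcpp::Named("error") = err);
  }
  vec grad(w.n_elem, fill::zeros);
  mat delta = (2.0 * (sw % resid) / wtot) % (out % (1.0 - out));
  // gradient layout mirrors the flat vector: weights first, then biases
  uword wpos = 0;
  std::vector<uword> woff(L), boff(L);
  for (int l = 0; l < L; ++l) {
    woff[l] = wpos;
    wpos += (uword)sizes[l] * sizes[l + 1];
  }
  for (int l = 0; l < L; ++l) {
    boff[l] = wpos;
    wpos += sizes[l + 1];
  }
  for (int l = L - 1; l >= 0; --l) {
    mat gW = acts[l].t() * delta;
    grad.subvec(woff[l], woff[l] + gW.n_elem - 1) = vectorise(gW);
    grad.subvec(boff[l], boff[l] + delta.n_cols - 1) = sum(delta, 0).t();
    if (l > 0) {
      delta = (delta * W[l].t()) % (acts[l] % (1.0 - acts[l]));
    }
  }
  return Rcpp::List::create(Rcpp::Named("error") = err,
                            Rcpp::Named("grad") = grad);
}
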