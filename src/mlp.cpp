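// Loss/gradient/prediction for the shallow fully connected classifiers.
// Parameters are packed layer by layer: W (column-major), then b.
// Hidden activations are ReLU; output is 2-way softmax; loss is mean
// cross-entropy plus (lambda/2)*||W||^2 on the weights (not biases).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void unpack(const arma::vec& theta, const arma::ivec& sizes,
                   std::vector<arma::mat>& Ws, std::vector<arma::rowvec>& bs) {
  int L = sizes.n_elem - 1;
  Ws.resize(L); bs.resize(L);
  long off = 0;
  for (int l = 0; l < L; ++l) {
    int in = sizes[l], out = sizes[l + 1];
    Ws[l] = arma::reshape(theta.subvec(off, off + (long)in * out - 1), in, out);
    off += (long)in * out;
    bs[l] = theta.subvec(off, off + out - 1).t();
    off += out;
  }
}

static arma::mat forward_all(const arma::mat& X,
                             const std::vector<arma::mat>& Ws,
                             const std::vector<arma::rowvec>& bs,
                             std::vector<arma::mat>* acts) {
  arma::mat A = X;
  int L = Ws.size();
  if (acts) acts->push_back(A);
  for (int l = 0; l < L; ++l) {
    A = A * Ws[l];
    A.each_row() += bs[l];
    if (l < L - 1) { A = arma::clamp(A, 0.0, arma::datum::inf); }
    if (acts && l < L - 1) acts->push_back(A);
  }
  // softmax rows
  arma::vec m = arma::max(A, 1);
  A.each_col() -= m;
  A = arma::exp(A);
  arma::vec s = arma::sum(A, 1);
  A.each_col() /= s;
  return A;
}

// [[Rcpp::export(name = ".mlpLossGrad")]]
List mlp_loss_grad(NumericVector theta_, NumericMatrix X_, IntegerVector y,
                   IntegerVector sizes_, double lambda) {
  arma::vec theta(theta_.begin(), theta_.size(), false);
  arma::mat X(X_.begin(), X_.nrow(), X_.ncol(), false);
  arma::ivec sizes(sizes_.size());
  for (int i = 0; i < sizes_.size(); ++i) sizes[i] = sizes_[i];
  int n = X.n_rows, L = sizes.n_elem - 1;

  std::vector<arma::mat> Ws; std::vector<arma::rowvec> bs;
  unpack(theta, sizes, Ws, bs);
  std::vector<arma::mat> acts;
  arma::mat P = forward_all(X, Ws, bs, &acts);

  double loss = 0.0;
  for (int i = 0; i < n; ++i)
    loss -= std::log(std::max(P(i, y[i]), 1e-300));
  loss /= n;
  for (int l = 0; l < L; ++l)
    loss += 0.5 * lambda * arma::accu(arma::square(Ws[l]));

  // backprop
  arma::mat D = P;
  for (int i = 0; i < n; ++i) D(i, y[i]) -= 1.0;
  D /= n;

  arma::vec grad(theta.n_elem, arma::fill::zeros);
  long off = theta.n_elem;
  for (int l = L - 1; l >= 0; --l) {
    int in = sizes[l], out = sizes[l + 1];
    arma::mat dW = acts[l].t() * D + lambda * Ws[l];
    arma::rowvec db = arma::sum(D, 0);
    off -= out;
    grad.subvec(off, off + out - 1) = db.t();
    off -= (long)in * out;
    grad.subvec(off, off + (long)in * out - 1) = arma::vectorise(dW);
    if (l > 0) {
      D = D * Ws[l].t();
      D.elem(arma::find(acts[l] <= 0.0)).zeros();
    }
  }
  return List::create(_["loss"] = loss,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export(name = ".mlpPredict")]]
NumericMatrix mlp_predict(NumericVector theta_, NumericMatrix X_,
                          IntegerVector sizes_) {
  arma::vec theta(theta_.begin(), theta_.size(), false);
  arma::mat X(X_.begin(), X_.nrow(), X_.ncol(), false);
  arma::ivec sizes(sizes_.size());
  for (int i = 0; i < sizes_.size(); ++i) sizes[i] = sizes_[i];
  std::vector<arma::mat> Ws; std::vector<arma::rowvec> bs;
  unpack(theta, sizes, Ws, bs);
  arma::mat P = forward_all(X, Ws, bs, nullptr);
  return wrap(P);
}
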