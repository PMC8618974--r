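// Single-hidden-layer perceptron for REE regression.
// Full-batch Adam on standardized inputs/targets; optional early stopping on
// a held-out slice of the training rows. Kept in C++ because the genetic
// selector's fitness function trains thousands of these models per run.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat act(const mat& z, int activation) {
  if (activation == 0) return tanh(z);
  return 1.0 / (1.0 + exp(-z));       // logistic
}

static mat act_grad(const mat& a, int activation) {
  if (activation == 0) return 1.0 - square(a);
  return a % (1.0 - a);
}

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::vec& y, int hidden,
                         int activation, int max_epochs, double lr,
                         int patience, double val_fraction,
                         unsigned int seed) {
  const int n = X.n_rows, p = X.n_cols;
  std::mt19937 rng(seed);

  // deterministic validation split for early stopping
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::shuffle(perm.begin(), perm.end(), rng);
  int n_val = (val_fraction > 0) ? (int)std::floor(val_fraction * n) : 0;
  if (n_val < 3) n_val = 0;           // too small to be a useful monitor
  int n_tr = n - n_val;
  uvec tr_idx(n_tr), va_idx(std::max(n_val, 1));
  for (int i = 0; i < n_tr; ++i) tr_idx[i] = perm[i];
  for (int i = 0; i < n_val; ++i) va_idx[i] = perm[n_tr + i];
  mat Xtr = X.rows(tr_idx);
  vec ytr = y.elem(tr_idx);
  mat Xva; vec yva;
  if (n_val > 0) { Xva = X.rows(va_idx); yva = y.elem(va_idx); }

  // Glorot-style uniform init
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  double r1 = std::sqrt(6.0 / (p + hidden));
  double r2 = std::sqrt(6.0 / (hidden + 1));
  mat W1(p, hidden); vec b1(hidden, fill::zeros);
  vec w2(hidden); double b2 = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < hidden; ++j) W1(i, j) = r1 * unif(rng);
  for (int j = 0; j < hidden; ++j) w2[j] = r2 * unif(rng);

  // Adam state
  mat mW1(p, hidden, fill::zeros), vW1(p, hidden, fill::zeros);
  vec mb1(hidden, fill::zeros), vb1(hidden, fill::zeros);
  vec mw2(hidden, fill::zeros), vw2(hidden, fill::zeros);
  double mb2 = 0, vb2 = 0;
  const double be1 = 0.9, be2 = 0.999, eps = 1e-8;

  mat bW1 = W1; vec bb1 = b1; vec bw2 = w2; double bb2 = b2;
  double best_val = datum::inf;
  int since_best = 0, epochs_run = 0;
  const double ntr_d = (double)n_tr;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    mat a1 = act(Xtr * W1 + repmat(b1.t(), n_tr, 1), activation);
    vec yhat = a1 * w2 + b2;
    vec err = yhat - ytr;

    vec d_out = 2.0 * err / ntr_d;
    vec gw2 = a1.t() * d_out;
    double gb2 = accu(d_out);
    mat d1 = (d_out * w2.t()) % act_grad(a1, activation);
    mat gW1 = Xtr.t() * d1;
    vec gb1 = sum(d1, 0).t();

    double c1 = 1.0 - std::pow(be1, epoch), c2 = 1.0 - std::pow(be2, epoch);
    mW1 = be1 * mW1 + (1 - be1) * gW1; vW1 = be2 * vW1 + (1 - be2) * square(gW1);
    W1 -= lr * (mW1 / c1) / (sqrt(vW1 / c2) + eps);
    mb1 = be1 * mb1 + (1 - be1) * gb1; vb1 = be2 * vb1 + (1 - be2) * square(gb1);
    b1 -= lr * (mb1 / c1) / (sqrt(vb1 / c2) + eps);
    mw2 = be1 * mw2 + (1 - be1) * gw2; vw2 = be2 * vw2 + (1 - be2) * square(gw2);
    w2 -= lr * (mw2 / c1) / (sqrt(vw2 / c2) + eps);
    mb2 = be1 * mb2 + (1 - be1) * gb2; vb2 = be2 * vb2 + (1 - be2) * gb2 * gb2;
    b2 -= lr * (mb2 / c1) / (std::sqrt(vb2 / c2) + eps);

    epochs_run = epoch;
    if (n_val > 0) {
      mat av = act(Xva * W1 + repmat(b1.t(), n_val, 1), activation);
      vec ev = av * w2 + b2 - yva;
      double val = dot(ev, ev) / n_val;
      if (val < best_val - 1e-12) {
        best_val = val; since_best = 0;
        bW1 = W1; bb1 = b1; bw2 = w2; bb2 = b2;
      } else if (++since_best >= patience) break;
    }
  }
  if (n_val == 0) { bW1 = W1; bb1 = b1; bw2 = w2; bb2 = b2; }

  return Rcpp::List::create(
    Rcpp::Named("W1") = bW1, Rcpp::Named("b1") = bb1,
    Rcpp::Named("w2") = bw2, Rcpp::Named("b2") = bb2,
    Rcpp::Named("epochs") = epochs_run,
    Rcpp::Named("val_mse") = (n_val > 0) ? best_val : NA_REAL);
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const arma::mat& X, const arma::mat& W1,
                          const arma::vec& b1, const arma::vec& w2, double b2,
                          int activation) {
  mat a1 = act(X * W1 + repmat(b1.t(), X.n_rows, 1), activation);
  return a1 * w2 + b2;
}
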