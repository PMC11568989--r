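// Single-hidden-layer perceptron for small tabular cohorts: ReLU hidden
// layer, sigmoid output, log loss with L2 penalty, trained by Adam or
// momentum SGD under a hard epoch cap. Self-contained RNG (no R RNG state)
// so training is a pure function of (data, config, seed).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double glorot_bound(int fan_in, int fan_out) {
  return std::sqrt(6.0 / (fan_in + fan_out));
}

// [[Rcpp::export(name = ".mlp_train_cpp")]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                         int hidden, double alpha, int max_epochs,
                         double learning_rate, int batch_size,
                         std::string solver, double momentum,
                         double tol, int n_iter_no_change,
                         int seed) {
  const int n = X.n_rows, d = X.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(-1.0, 1.0);

  mat W1(d, hidden), W2(hidden, 1);
  vec b1(hidden, fill::zeros), b2(1, fill::zeros);
  const double bnd1 = glorot_bound(d, hidden), bnd2 = glorot_bound(hidden, 1);
  for (auto& v : W1) v = bnd1 * unif(rng);
  for (auto& v : W2) v = bnd2 * unif(rng);

  // optimizer state
  mat mW1(size(W1), fill::zeros), vW1(size(W1), fill::zeros);
  mat mW2(size(W2), fill::zeros), vW2(size(W2), fill::zeros);
  vec mb1(size(b1), fill::zeros), vb1(size(b1), fill::zeros);
  vec mb2(size(b2), fill::zeros), vb2(size(b2), fill::zeros);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t_adam = 0;

  const int bs = std::min(batch_size, n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  double best_loss = datum::inf;
  int no_improve = 0;
  int epochs_run = 0;
  const bool adam = (solver == "adam");

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epoch_loss = 0.0;
    for (int start = 0; start < n; start += bs) {
      const int stop = std::min(start + bs, n);
      const int nb = stop - start;
      uvec rows(nb);
      for (int i = 0; i < nb; ++i) rows[i] = idx[start + i];
      mat Xb = X.rows(rows);
      vec yb = y(rows);

      mat Z1 = Xb * W1;
      Z1.each_row() += b1.t();
      mat A1 = clamp(Z1, 0.0, datum::inf);          // ReLU
      vec z2 = A1 * W2 + b2(0);
      vec p = 1.0 / (1.0 + exp(-z2));               // sigmoid

      // batch log loss + L2 (reference-implementation convention)
      vec pc = clamp(p, 1e-10, 1.0 - 1e-10);
      double loss = -mean(yb % log(pc) + (1.0 - yb) % log(1.0 - pc));
      loss += 0.5 * alpha * (accu(square(W1)) + accu(square(W2))) / nb;
      epoch_loss += loss * nb;

      vec delta2 = (p - yb) / nb;                   // dL/dz2
      mat gW2 = A1.t() * delta2 + (alpha / nb) * W2;
      vec gb2(1); gb2(0) = accu(delta2);
      mat delta1 = delta2 * W2.t();                 // nb x hidden
      delta1.elem(find(Z1 <= 0.0)).zeros();
      mat gW1 = Xb.t() * delta1 + (alpha / nb) * W1;
      vec gb1 = sum(delta1, 0).t();

      if (adam) {
        ++t_adam;
        const double bc1 = 1.0 - std::pow(beta1, (double)t_adam);
        const double bc2 = 1.0 - std::pow(beta2, (double)t_adam);
        auto step = [&](mat& W, mat& mW, mat& vW, const mat& g) {
          mW = beta1 * mW + (1.0 - beta1) * g;
          vW = beta2 * vW + (1.0 - beta2) * square(g);
          W -= learning_rate * (mW / bc1) / (sqrt(vW / bc2) + eps);
        };
        auto stepv = [&](vec& W, vec& mW, vec& vW, const vec& g) {
          mW = beta1 * mW + (1.0 - beta1) * g;
          vW = beta2 * vW + (1.0 - beta2) * square(g);
          W -= learning_rate * (mW / bc1) / (sqrt(vW / bc2) + eps);
        };
        step(W1, mW1, vW1, gW1); step(W2, mW2, vW2, gW2);
        stepv(b1, mb1, vb1, gb1); stepv(b2, mb2, vb2, gb2);
      } else {                                       // Nesterov momentum SGD
        auto step = [&](mat& W, mat& mW, const mat& g) {
          mW = momentum * mW - learning_rate * g;
          W += momentum * mW - learning_rate * g;
        };
        auto stepv = [&](vec& W, vec& mW, const vec& g) {
          mW = momentum * mW - learning_rate * g;
          W += momentum * mW - learning_rate * g;
        };
        step(W1, mW1, gW1); step(W2, mW2, gW2);
        stepv(b1, mb1, gb1); stepv(b2, mb2, gb2);
      }
    }
    epochs_run = epoch + 1;
    epoch_loss /= n;
    if (epoch_loss < best_loss - tol) {
      best_loss = epoch_loss;
      no_improve = 0;
    } else if (++no_improve >= n_iter_no_change) break;
  }

  return Rcpp::List::create(
    Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
    Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2,
    Rcpp::Named("epochs_run") = epochs_run,
    Rcpp::Named("final_loss") = best_loss);
}

// [[Rcpp::export(name = ".mlp_score_cpp")]]
arma::vec mlp_score_cpp(const arma::mat& X, const arma::mat& W1,
                        const arma::vec& b1, const arma::mat& W2,
                        const arma::vec& b2) {
  mat Z1 = X * W1;
  Z1.each_row() += b1.t();
  mat A1 = clamp(Z1, 0.0, datum::inf);
  vec z2 = A1 * W2 + b2(0);
  return 1.0 / (1.0 + exp(-z2));
}
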