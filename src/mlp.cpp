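// Training loop for the drug-target interaction network. All randomness
// (initialisation, epoch shuffling, dropout) is drawn from R's RNG so runs
// are reproducible from set.seed() and bit-identical on one thread. The R
// level keeps a pure-R forward pass used as an independent reference in the
// tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat he_init(int nin, int nout) {
  arma::mat W(nin, nout);
  double sd = std::sqrt(2.0 / nin);
  for (arma::uword j = 0; j < W.n_cols; ++j)
    for (arma::uword i = 0; i < W.n_rows; ++i)
      W(i, j) = R::rnorm(0.0, sd);
  return W;
}

static double bce(const arma::vec &phat, const arma::vec &y) {
  arma::vec p = arma::clamp(phat, 1e-7, 1.0 - 1e-7);
  return -arma::mean(y % arma::log(p) + (1.0 - y) % arma::log(1.0 - p));
}

// forward pass without dropout; returns output probabilities
static arma::vec forward_infer(const std::vector<arma::mat> &W,
                               const std::vector<arma::rowvec> &b,
                               const arma::mat &X) {
  arma::mat A = X;
  const size_t L = W.size();
  for (size_t l = 0; l < L; ++l) {
    A = A * W[l];
    A.each_row() += b[l];
    if (l + 1 < L) {
      A.transform([](double z) { return z > 0.0 ? z : 0.0; });
    } else {
      A.transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
    }
  }
  return A.col(0);
}

struct AdamState {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::rowvec> mb, vb;
  long t = 0;
};

// [[Rcpp::export(name = ".cpp_mlp_train")]]
List cpp_mlp_train(const arma::mat &X_train, const arma::vec &y_train,
                   const arma::mat &X_val, const arma::vec &y_val,
                   const IntegerVector &hidden, double dropout, double lr,
                   int epochs, int batch_size, double patience) {
  RNGScope rngScope;   // draw from (and advance) R's RNG

  const int n = X_train.n_rows;
  std::vector<int> sizes;
  sizes.push_back(X_train.n_cols);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(1);
  const size_t L = sizes.size() - 1;

  std::vector<arma::mat> W(L);
  std::vector<arma::rowvec> b(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = he_init(sizes[l], sizes[l + 1]);
    // near-zero output layer: training starts from the uninformative
    // predictor (p ~ 0.5, loss ~ log 2) regardless of network depth
    if (l + 1 == L) W[l] *= 0.01;
    b[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
  }
  AdamState st;
  st.mW.resize(L); st.vW.resize(L); st.mb.resize(L); st.vb.resize(L);
  for (size_t l = 0; l < L; ++l) {
    st.mW[l] = arma::mat(arma::size(W[l]), arma::fill::zeros);
    st.vW[l] = arma::mat(arma::size(W[l]), arma::fill::zeros);
    st.mb[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
    st.vb[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
  }

  std::vector<arma::mat> bestW = W;
  std::vector<arma::rowvec> bestb = b;
  double best_loss = R_PosInf;
  int best_epoch = 0, stall = 0, n_epochs_run = 0;

  std::vector<double> h_train_loss, h_train_acc, h_val_loss, h_val_acc;
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  std::vector<arma::mat> A(L + 1), mask(L);

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double run_loss = 0.0, run_acc = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n) - 1;
      arma::uvec idx(end - start + 1);
      for (int i = start; i <= end; ++i) idx(i - start) = perm[i];
      arma::mat Xb = X_train.rows(idx);
      arma::vec yb = y_train.elem(idx);
      const double m = (double)yb.n_elem;

      // forward with inverted dropout on hidden activations
      A[0] = Xb;
      for (size_t l = 0; l < L; ++l) {
        arma::mat Z = A[l] * W[l];
        Z.each_row() += b[l];
        if (l + 1 < L) {
          mask[l].set_size(arma::size(Z));
          if (dropout > 0) {
            const double keep = 1.0 - dropout;
            for (arma::uword k = 0; k < Z.n_elem; ++k) {
              double d = (unif_rand() < keep) ? 1.0 / keep : 0.0;
              mask[l](k) = (Z(k) > 0.0) ? d : 0.0;
            }
          } else {
            for (arma::uword k = 0; k < Z.n_elem; ++k)
              mask[l](k) = (Z(k) > 0.0) ? 1.0 : 0.0;
          }
          A[l + 1] = Z % mask[l];
        } else {
          Z.transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
          A[l + 1] = Z;
        }
      }
      arma::vec phat = A[L].col(0);
      run_loss += bce(phat, yb);
      run_acc += arma::mean(arma::conv_to<arma::vec>::from((phat >= 0.5) == (yb == 1.0)));
      ++n_batches;

      // backward
      arma::mat delta = (A[L] - arma::mat(yb)) / m;
      for (int l = (int)L - 1; l >= 0; --l) {
        arma::mat gW = A[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= mask[l - 1];
        }
        // Adam update for this layer (delta above used the pre-update W)
        {
          const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
          if (l == (int)L - 1) st.t += 1;   // one step per minibatch
          const double c1 = 1.0 - std::pow(beta1, (double)st.t);
          const double c2 = 1.0 - std::pow(beta2, (double)st.t);
          st.mW[l] = beta1 * st.mW[l] + (1.0 - beta1) * gW;
          st.vW[l] = beta2 * st.vW[l] + (1.0 - beta2) * arma::square(gW);
          W[l] -= lr * (st.mW[l] / c1) / (arma::sqrt(st.vW[l] / c2) + eps);
          st.mb[l] = beta1 * st.mb[l] + (1.0 - beta1) * gb;
          st.vb[l] = beta2 * st.vb[l] + (1.0 - beta2) * arma::square(gb);
          b[l] -= lr * (st.mb[l] / c1) / (arma::sqrt(st.vb[l] / c2) + eps);
        }
      }
    }

    arma::vec pv = forward_infer(W, b, X_val);
    double val_loss = bce(pv, y_val);
    double val_acc = arma::mean(arma::conv_to<arma::vec>::from((pv >= 0.5) == (y_val == 1.0)));
    h_train_loss.push_back(run_loss / n_batches);
    h_train_acc.push_back(run_acc / n_batches);
    h_val_loss.push_back(val_loss);
    h_val_acc.push_back(val_acc);
    n_epochs_run = epoch;

    if (val_loss < best_loss - 1e-12) {
      best_loss = val_loss;
      bestW = W; bestb = b;
      best_epoch = epoch;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }

  List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) {
    Wl[l] = wrap(bestW[l]);
    bl[l] = wrap(arma::vec(bestb[l].t()));
  }
  DataFrame history = DataFrame::create(
      _["epoch"] = seq_len(n_epochs_run),
      _["train_loss"] = h_train_loss, _["train_accuracy"] = h_train_acc,
      _["val_loss"] = h_val_loss, _["val_accuracy"] = h_val_acc);
  return List::create(_["W"] = Wl, _["b"] = bl, _["history"] = history,
                      _["best_epoch"] = best_epoch);
}

// [[Rcpp::export(name = ".cpp_mlp_predict")]]
NumericVector cpp_mlp_predict(const List &W, const List &b, const arma::mat &X) {
  std::vector<arma::mat> Wv;
  std::vector<arma::rowvec> bv;
  for (int l = 0; l < W.size(); ++l) {
    Wv.push_back(as<arma::mat>(W[l]));
    bv.push_back(arma::rowvec(as<arma::vec>(b[l]).t()));
  }
  return wrap(forward_infer(Wv, bv, X));
}
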