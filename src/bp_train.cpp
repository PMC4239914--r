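#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Sequential (per-sample) backpropagation with momentum for a 3-layer
// sigmoid network. Output-layer delta is (o - y), the sigmoid delta rule;
// the monitored training error is the mean squared error over the full set,
// checked after each epoch against target_mse. Presentation order per epoch
// is supplied by the caller (seeded in R), so training is deterministic.
//
// X: m x p inputs, Y: m x q one-of-q targets, order: max_epochs x m matrix
// of 1-based presentation orders. Weight matrices are modified copies.
// [[Rcpp::export]]
List bp_train_cpp(NumericMatrix X, NumericMatrix Y,
                  NumericMatrix W1_, NumericVector b1_,
                  NumericMatrix W2_, NumericVector b2_,
                  IntegerMatrix order,
                  double lr, double momentum,
                  double target_mse, int max_epochs) {
  const int m = X.nrow(), p = X.ncol(), q = Y.ncol();
  const int h = W1_.ncol();
  NumericMatrix W1m = clone(W1_), W2m = clone(W2_);
  NumericVector b1v = clone(b1_), b2v = clone(b2_);
  double *W1 = REAL(W1m), *W2 = REAL(W2m), *b1 = REAL(b1v), *b2 = REAL(b2v);
  const double *Xp = REAL(X), *Yp = REAL(Y);
  const int *ord = INTEGER(order);
  const int n_ep = order.nrow();

  // row-major copies of X and Y for contiguous per-sample access
  std::vector<double> Xr((size_t)m * p), Yr((size_t)m * q);
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < m; ++i) Xr[(size_t)i * p + k] = Xp[i + (size_t)k * m];
  for (int c = 0; c < q; ++c)
    for (int i = 0; i < m; ++i) Yr[(size_t)i * q + c] = Yp[i + (size_t)c * m];

  std::vector<double> dW1((size_t)p * h, 0.0), db1(h, 0.0),
      dW2((size_t)h * q, 0.0), db2(q, 0.0), hid(h), eo(q), eh(h);

  double mse = R_PosInf;
  int epoch = 0;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    for (int ii = 0; ii < m; ++ii) {
      const int i = ord[(epoch - 1) + (size_t)ii * n_ep] - 1;
      const double *xi = &Xr[(size_t)i * p];
      const double *yi = &Yr[(size_t)i * q];
      for (int j = 0; j < h; ++j) {
        double z = b1[j];
        const double *w1j = W1 + (size_t)j * p;   // column j of W1 (p x h)
        for (int k = 0; k < p; ++k) z += xi[k] * w1j[k];
        hid[j] = sigmoid(z);
      }
      for (int c = 0; c < q; ++c) {
        double z = b2[c];
        const double *w2c = W2 + (size_t)c * h;
        for (int j = 0; j < h; ++j) z += hid[j] * w2c[j];
        eo[c] = sigmoid(z) - yi[c];
      }
      for (int j = 0; j < h; ++j) {
        double s = 0.0;
        for (int c = 0; c < q; ++c) s += W2[j + (size_t)c * h] * eo[c];
        eh[j] = s * hid[j] * (1.0 - hid[j]);
      }
      for (int c = 0; c < q; ++c) {
        double *w2c = W2 + (size_t)c * h;
        double *d2c = &dW2[(size_t)c * h];
        const double le = lr * eo[c];
        for (int j = 0; j < h; ++j) {
          d2c[j] = momentum * d2c[j] - le * hid[j];
          w2c[j] += d2c[j];
        }
        db2[c] = momentum * db2[c] - le;
        b2[c] += db2[c];
      }
      for (int j = 0; j < h; ++j) {
        double *w1j = W1 + (size_t)j * p;
        double *d1j = &dW1[(size_t)j * p];
        const double le = lr * eh[j];
        for (int k = 0; k < p; ++k) {
          d1j[k] = momentum * d1j[k] - le * xi[k];
          w1j[k] += d1j[k];
        }
        db1[j] = momentum * db1[j] - le;
        b1[j] += db1[j];
      }
    }
    // full-set MSE after the epoch
    double sse = 0.0;
    for (int i = 0; i < m; ++i) {
      const double *xi = &Xr[(size_t)i * p];
      const double *yi = &Yr[(size_t)i * q];
      for (int j = 0; j < h; ++j) {
        double z = b1[j];
        const double *w1j = W1 + (size_t)j * p;
        for (int k = 0; k < p; ++k) z += xi[k] * w1j[k];
        hid[j] = sigmoid(z);
      }
      for (int c = 0; c < q; ++c) {
        double z = b2[c];
        const double *w2c = W2 + (size_t)c * h;
        for (int j = 0; j < h; ++j) z += hid[j] * w2c[j];
        double e = sigmoid(z) - yi[c];
        sse += e * e;
      }
    }
    mse = sse / (double)((size_t)m * q);
    if (mse <= target_mse) break;
  }
  if (epoch > max_epochs) epoch = max_epochs;
  return List::create(_["W1"] = W1m, _["b1"] = b1v, _["W2"] = W2m, _["b2"] = b2v,
                      _["mse"] = mse, _["epochs"] = epoch);
}

// Forward pass for a trained net: returns m x q sigmoid outputs.
// [[Rcpp::export]]
NumericMatrix bp_predict_cpp(NumericMatrix X, NumericMatrix W1_,
                             NumericVector b1_, NumericMatrix W2_,
                             NumericVector b2_) {
  const int m = X.nrow(), p = X.ncol(), h = W1_.ncol(), q = W2_.ncol();
  const double *Xp = REAL(X), *W1 = REAL(W1_), *W2 = REAL(W2_);
  const double *b1 = REAL(b1_), *b2 = REAL(b2_);
  NumericMatrix out(m, q);
  std::vector<double> hid(h);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < h; ++j) {
      double z = b1[j];
      const double *w1j = W1 + (size_t)j * p;
      for (int k = 0; k < p; ++k) z += Xp[i + (size_t)k * m] * w1j[k];
      hid[j] = sigmoid(z);
    }
    for (int c = 0; c < q; ++c) {
      double z = b2[c];
      const double *w2c = W2 + (size_t)c * h;
      for (int j = 0; j < h; ++j) z += hid[j] * w2c[j];
      out(i, c) = sigmoid(z);
    }
  }
  return out;
}
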