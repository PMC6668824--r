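#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bipolar logistic 2/(1+exp(-x)) - 1 == tanh(x/2); derivative (1 - f^2)/2.
static inline double act(double x) { return std::tanh(0.5 * x); }

// One full-batch forward/backward pass over the data (Xt is p x n,
// column i = row i of the n x p input, so each case is contiguous).
// Accumulates gradients of the summed squared error sum_i (t_i - o_i)^2
// into gW1 (h x p), gb1, gw2, gb2 and returns the error.
static double pass(const double* Xt, const double* y, int n, int p, int h,
                   const std::vector<double>& W1,
                   const std::vector<double>& b1,
                   const std::vector<double>& w2, double b2,
                   std::vector<double>& gW1, std::vector<double>& gb1,
                   std::vector<double>& gw2, double& gb2,
                   std::vector<double>& hid, std::vector<double>& out) {
  std::fill(gW1.begin(), gW1.end(), 0.0);
  std::fill(gb1.begin(), gb1.end(), 0.0);
  std::fill(gw2.begin(), gw2.end(), 0.0);
  gb2 = 0.0;
  double err = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xt[(size_t)i * p];
    // forward
    double net_o = b2;
    for (int j = 0; j < h; ++j) {
      double s = b1[j];
      const double* wj = &W1[(size_t)j * p];
      for (int k = 0; k < p; ++k) s += wj[k] * xi[k];
      double hj = act(s);
      hid[j] = hj;
      net_o = net_o + w2[j] * hj;
    }
    double o = act(net_o);
    out[i] = o;
    double e = y[i] - o;
    err += e * e;
    // backward
    double d_o = -2.0 * e * 0.5 * (1.0 - o * o);  // dE/dnet_o
    gb2 += d_o;
    for (int j = 0; j < h; ++j) {
      gw2[j] += d_o * hid[j];
      double d_h = d_o * w2[j] * 0.5 * (1.0 - hid[j] * hid[j]);
      gb1[j] += d_h;
      double* gj = &gW1[(size_t)j * p];
      for (int k = 0; k < p; ++k) gj[k] += d_h * xi[k];
    }
  }
  return err;
}

// [[Rcpp::export(name = ".cpp_nn_grad")]]
List cpp_nn_grad(NumericMatrix X, NumericVector y, NumericMatrix W1,
                 NumericVector b1, NumericVector w2, double b2) {
  int n = X.nrow(), p = X.ncol(), h = W1.nrow();
  if (W1.ncol() != p) stop("W1 must be h x p");
  std::vector<double> vW1(h * (size_t)p), vb1(b1.begin(), b1.end()),
      vw2(w2.begin(), w2.end());
  for (int j = 0; j < h; ++j)
    for (int k = 0; k < p; ++k) vW1[(size_t)j * p + k] = W1(j, k);
  std::vector<double> Xt((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) Xt[(size_t)i * p + k] = X(i, k);
  std::vector<double> gW1(h * (size_t)p), gb1(h), gw2(h), hid(h), out(n);
  double gb2 = 0.0;
  double err = pass(Xt.data(), y.begin(), n, p, h, vW1, vb1, vw2, b2,
                    gW1, gb1, gw2, gb2, hid, out);
  NumericMatrix gW1m(h, p);
  for (int j = 0; j < h; ++j)
    for (int k = 0; k < p; ++k) gW1m(j, k) = gW1[(size_t)j * p + k];
  return List::create(_["error"] = err, _["gW1"] = gW1m,
                      _["gb1"] = NumericVector(gb1.begin(), gb1.end()),
                      _["gw2"] = NumericVector(gw2.begin(), gw2.end()),
                      _["gb2"] = gb2,
                      _["output"] = NumericVector(out.begin(), out.end()));
}

// [[Rcpp::export(name = ".cpp_nn_train")]]
List cpp_nn_train(NumericMatrix X, NumericVector y, NumericMatrix W1,
                  NumericVector b1, NumericVector w2, double b2,
                  double lr, int max_epochs, double tol) {
  int n = X.nrow(), p = X.ncol(), h = W1.nrow();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (W1.ncol() != p) stop("W1 must be h x p");
  std::vector<double> vW1(h * (size_t)p), vb1(b1.begin(), b1.end()),
      vw2(w2.begin(), w2.end());
  double vb2 = b2;
  for (int j = 0; j < h; ++j)
    for (int k = 0; k < p; ++k) vW1[(size_t)j * p + k] = W1(j, k);
  std::vector<double> Xt((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) Xt[(size_t)i * p + k] = X(i, k);
  std::vector<double> gW1(h * (size_t)p), gb1(h), gw2(h), hid(h), out(n);
  std::vector<double> errors;
  errors.reserve(max_epochs);
  double gb2 = 0.0, prev = R_PosInf;
  bool converged = false;
  int epoch = 0;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    double err = pass(Xt.data(), y.begin(), n, p, h, vW1, vb1, vw2, vb2,
                      gW1, gb1, gw2, gb2, hid, out);
    if (!std::isfinite(err))
      stop("non-finite training error at epoch %d", epoch + 1);
    errors.push_back(err);
    if (std::fabs(prev - err) < tol) { converged = true; ++epoch; break; }
    prev = err;
    for (size_t q = 0; q < vW1.size(); ++q) vW1[q] -= lr * gW1[q];
    for (int j = 0; j < h; ++j) {
      vb1[j] -= lr * gb1[j];
      vw2[j] -= lr * gw2[j];
    }
    vb2 -= lr * gb2;
  }
  NumericMatrix W1o(h, p);
  for (int j = 0; j < h; ++j)
    for (int k = 0; k < p; ++k) W1o(j, k) = vW1[(size_t)j * p + k];
  return List::create(
      _["W1"] = W1o, _["b1"] = NumericVector(vb1.begin(), vb1.end()),
      _["w2"] = NumericVector(vw2.begin(), vw2.end()), _["b2"] = vb2,
      _["errors"] = NumericVector(errors.begin(), errors.end()),
      _["epochs"] = epoch, _["converged"] = converged);
}
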