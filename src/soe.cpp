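// Soft ordinal embedding: full-batch gradient descent on the squared
// hinge loss
//   L(X) = sum_t max(0, delta + ||x_a - x_w||^2 - ||x_a - x_l||^2)^2
// over triplets t = (anchor a, winner w, loser l).  Backtracking line
// search keeps the loss non-increasing across accepted iterations; the
// optimization stops when the relative loss change falls below `tol`.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static double soe_loss(const std::vector<double>& X, int n, int d,
                       const IntegerMatrix& trip, double delta) {
  double loss = 0.0;
  const int nt = trip.nrow();
  for (int t = 0; t < nt; ++t) {
    const int a = trip(t, 0), w = trip(t, 1), l = trip(t, 2);
    double dw = 0.0, dl = 0.0;
    for (int k = 0; k < d; ++k) {
      const double ew = X[a * d + k] - X[w * d + k];
      const double el = X[a * d + k] - X[l * d + k];
      dw += ew * ew;
      dl += el * el;
    }
    const double h = delta + dw - dl;
    if (h > 0.0) loss += h * h;
  }
  return loss;
}

static void soe_grad(const std::vector<double>& X, int n, int d,
                     const IntegerMatrix& trip, double delta,
                     std::vector<double>& G) {
  std::fill(G.begin(), G.end(), 0.0);
  const int nt = trip.nrow();
  for (int t = 0; t < nt; ++t) {
    const int a = trip(t, 0), w = trip(t, 1), l = trip(t, 2);
    double dw = 0.0, dl = 0.0;
    for (int k = 0; k < d; ++k) {
      const double ew = X[a * d + k] - X[w * d + k];
      const double el = X[a * d + k] - X[l * d + k];
      dw += ew * ew;
      dl += el * el;
    }
    const double h = delta + dw - dl;
    if (h <= 0.0) continue;
    const double c = 4.0 * h;  // d(h^2)/dh * d(dw - dl)/d(.) coefficients
    for (int k = 0; k < d; ++k) {
      const double ew = X[a * d + k] - X[w * d + k];
      const double el = X[a * d + k] - X[l * d + k];
      G[a * d + k] += c * (ew - el);
      G[w * d + k] -= c * ew;
      G[l * d + k] += c * el;
    }
  }
}

// [[Rcpp::export(name = ".soe_fit_cpp")]]
List soe_fit_cpp(NumericMatrix X0, IntegerMatrix triplets, double delta,
                 double tol, int max_iter) {
  const int n = X0.nrow(), d = X0.ncol();
  std::vector<double> X(n * d), G(n * d), Xtry(n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) X[i * d + k] = X0(i, k);

  double loss = soe_loss(X, n, d, triplets, delta);
  double step = 1.0;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    if (loss <= 0.0) { converged = true; break; }
    soe_grad(X, n, d, triplets, delta, G);
    double gnorm2 = 0.0;
    for (size_t j = 0; j < G.size(); ++j) gnorm2 += G[j] * G[j];
    if (gnorm2 < 1e-30) { converged = true; break; }

    // backtracking line search (Armijo, c1 = 1e-4)
    double new_loss = loss;
    bool accepted = false;
    step *= 2.0;  // allow the step to grow again after cautious phases
    for (int bt = 0; bt < 60; ++bt) {
      for (size_t j = 0; j < X.size(); ++j) Xtry[j] = X[j] - step * G[j];
      new_loss = soe_loss(Xtry, n, d, triplets, delta);
      if (new_loss <= loss - 1e-4 * step * gnorm2) { accepted = true; break; }
      step *= 0.5;
    }
    if (!accepted) break;  // no further descent possible at machine precision
    X.swap(Xtry);
    const double rel = (loss - new_loss) / std::max(loss, 1e-300);
    loss = new_loss;
    if (rel < tol) { converged = true; ++iter; break; }
  }

  NumericMatrix Xout(n, d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) Xout(i, k) = X[i * d + k];
  return List::create(_["X"] = Xout, _["loss"] = loss,
                      _["iterations"] = iter, _["converged"] = converged);
}
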