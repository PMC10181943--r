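// Multiplicative-update ARD-NMF: nonnegative factorization V ~ W * H with a
// shared inverse-gamma relevance prior per component, so that unneeded
// components are shrunk away and the effective rank is learned from the data.
//
// divergence: 0 = gaussian (half squared Frobenius), 1 = poisson (KL)
// prior:      0 = half-normal (L2 penalty),          1 = exponential (L1)
//
// Every update is a majorization-minimization step, so the MAP objective
// (data divergence / phi + component penalties + relevance log terms) is
// non-increasing. For poisson divergence with the half-normal prior the
// closed-form root of the quadratic majorizer is used; the other three
// combinations admit the usual multiplicative ratio updates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static double component_penalty(const mat& W, const mat& H, int prior, uword k) {
  if (prior == 1)
    return accu(W.col(k)) + accu(H.row(k));
  return 0.5 * accu(square(W.col(k))) + 0.5 * accu(square(H.row(k)));
}

// [[Rcpp::export(name = ".ardnmf_fit")]]
List ardnmf_fit(const arma::mat& V, arma::mat W, arma::mat H,
                int divergence, int prior,
                double a, double b, double phi,
                double tol, int max_iter, double eps) {
  const uword F = V.n_rows, N = V.n_cols, K = W.n_cols;
  const double Cconst = (prior == 1)
      ? static_cast<double>(F + N) + a + 1.0
      : 0.5 * static_cast<double>(F + N) + a + 1.0;

  vec lambda(K, fill::ones);
  auto update_lambda = [&]() {
    for (uword k = 0; k < K; ++k) {
      lambda(k) = (component_penalty(W, H, prior, k) + b) / Cconst;
      if (lambda(k) < eps) lambda(k) = eps;
    }
  };

  auto objective = [&]() {
    mat WH = W * H;
    WH.for_each([&](double& x) { if (x < eps) x = eps; });
    double D = 0.0;
    if (divergence == 0) {
      D = 0.5 * accu(square(V - WH));
    } else {
      for (uword j = 0; j < N; ++j)
        for (uword i = 0; i < F; ++i) {
          const double v = V(i, j), m = WH(i, j);
          D += (v > 0.0) ? v * std::log(v / m) - v + m : m;
        }
    }
    double pen = 0.0;
    for (uword k = 0; k < K; ++k)
      pen += (component_penalty(W, H, prior, k) + b) / lambda(k)
           + Cconst * std::log(lambda(k));
    return D / phi + pen;
  };

  update_lambda();
  double obj_prev = objective();
  std::vector<double> trace;
  trace.reserve(1024);
  trace.push_back(obj_prev);

  bool converged = false;
  int it = 0;
  const double vnorm2 = accu(square(V));
  bool have_cheap_obj = false;
  double cheap_D = 0.0;

  for (it = 1; it <= max_iter; ++it) {
    const vec inv_lambda = 1.0 / lambda;

    if (divergence == 0) {
      // gaussian
      mat num = V * H.t();
      mat den = W * (H * H.t());
      if (prior == 0) den += phi * (W * diagmat(inv_lambda));
      else            den.each_row() += phi * inv_lambda.t();
      W %= num / (den + eps);

      const mat WtV = W.t() * V;
      const mat WtW = W.t() * W;
      mat denH = WtW * H;
      if (prior == 0) denH += phi * (diagmat(inv_lambda) * H);
      else            denH.each_col() += phi * inv_lambda;
      H %= WtV / (denH + eps);

      // ||V - WH||^2 from cached Gram matrices (WtV, WtW valid for the
      // current W; H just updated)
      cheap_D = 0.5 * (vnorm2 - 2.0 * accu(WtV % H) + accu(WtW % (H * H.t())));
      if (cheap_D < 0.0) cheap_D = 0.0;
      have_cheap_obj = true;
    } else {
      // poisson
      mat WH = W * H;
      WH.for_each([&](double& x) { if (x < eps) x = eps; });
      mat R = V / WH;
      const mat numW = W % (R * H.t());          // MM numerator p = w_old * sum
      const rowvec hsum = sum(H, 1).t();
      if (prior == 1) {
        mat den(F, K);
        den.each_row() = hsum + phi * inv_lambda.t();
        W = numW / (den + eps);
      } else {
        // minimize q*w/phi - p*log(w)/phi + w^2/(2*lambda):
        // w = lambda/2 * (-q/phi + sqrt(q^2/phi^2 + 4 p/(phi*lambda)))
        for (uword k = 0; k < K; ++k) {
          const double q = hsum(k) / phi, lam = lambda(k);
          vec p = numW.col(k) / phi;
          W.col(k) = 0.5 * lam * (-q + sqrt(q * q + (4.0 / lam) * p));
        }
      }

      WH = W * H;
      WH.for_each([&](double& x) { if (x < eps) x = eps; });
      R = V / WH;
      const mat numH = H % (W.t() * R);
      const vec wsum = sum(W, 0).t();
      if (prior == 1) {
        mat den(K, N);
        den.each_col() = wsum + phi * inv_lambda;
        H = numH / (den + eps);
      } else {
        for (uword k = 0; k < K; ++k) {
          const double q = wsum(k) / phi, lam = lambda(k);
          rowvec p = numH.row(k) / phi;
          H.row(k) = 0.5 * lam * (-q + sqrt(q * q + (4.0 / lam) * p));
        }
      }
    }

    update_lambda();
    double obj;
    if (have_cheap_obj) {
      double pen = 0.0;
      for (uword k = 0; k < K; ++k)
        pen += (component_penalty(W, H, prior, k) + b) / lambda(k)
             + Cconst * std::log(lambda(k));
      obj = cheap_D / phi + pen;
    } else {
      obj = objective();
    }
    trace.push_back(obj);
    const double rel = std::fabs(obj_prev - obj) / (std::fabs(obj_prev) + eps);
    obj_prev = obj;
    if (it > 20 && rel < tol) { converged = true; break; }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["W"] = W,
    _["H"] = H,
    _["lambda"] = NumericVector(lambda.begin(), lambda.end()),
    _["objective_trace"] = NumericVector(trace.begin(), trace.end()),
    _["converged"] = converged,
    _["n_iter"] = static_cast<int>(trace.size()) - 1);
}
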