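// Compiled numerical kernels: the exact 1-D total-variation proximal
// operator (Condat's direct algorithm), the composite row-wise proximal
// operator of the fused-lasso penalty, and block coordinate descent for
// the multi-task group LASSO.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exact solution of min_x 0.5 ||x - y||^2 + lam * sum_i |x[i+1] - x[i]|
// (Condat 2013, direct non-iterative algorithm).
static void tv1d_condat(const double* y, double* x, int n, double lam) {
  if (n == 0) return;
  if (n == 1 || lam <= 0.0) {
    for (int i = 0; i < n; ++i) x[i] = y[i];
    return;
  }
  int k = 0, k0 = 0, km = 0, kp = 0;
  double vmin = y[0] - lam, vmax = y[0] + lam;
  double umin = lam, umax = -lam;
  for (;;) {
    if (k == n - 1) {
      if (umin < 0.0) {
        for (int i = k0; i <= km; ++i) x[i] = vmin;
        k0 = km + 1;
        k = k0; km = k0;
        vmin = y[k];
        umin = lam;
        umax = y[k] + lam - vmax;
      } else if (umax > 0.0) {
        for (int i = k0; i <= kp; ++i) x[i] = vmax;
        k0 = kp + 1;
        k = k0; kp = k0;
        vmax = y[k];
        umax = -lam;
        umin = y[k] - lam - vmin;
      } else {
        double v = vmin + umin / (k - k0 + 1);
        for (int i = k0; i <= k; ++i) x[i] = v;
        return;
      }
      if (k == n - 1) {
        // re-enter terminal handling with refreshed state
        continue;
      }
    }
    if (y[k + 1] + umin < vmin - lam) {          // negative jump
      for (int i = k0; i <= km; ++i) x[i] = vmin;
      k0 = km + 1;
      k = k0; km = k0; kp = k0;
      vmin = y[k];
      vmax = y[k] + 2.0 * lam;
      umin = lam;
      umax = -lam;
    } else if (y[k + 1] + umax > vmax + lam) {   // positive jump
      for (int i = k0; i <= kp; ++i) x[i] = vmax;
      k0 = kp + 1;
      k = k0; km = k0; kp = k0;
      vmin = y[k] - 2.0 * lam;
      vmax = y[k];
      umin = lam;
      umax = -lam;
    } else {                                     // no jump
      ++k;
      umin += y[k] - vmin;
      umax += y[k] - vmax;
      if (umin >= lam) {
        vmin += (umin - lam) / (k - k0 + 1);
        umin = lam;
        km = k;
      }
      if (umax <= -lam) {
        vmax += (umax + lam) / (k - k0 + 1);
        umax = -lam;
        kp = k;
      }
    }
  }
}

// [[Rcpp::export(name = ".prox_tv1d_cpp")]]
arma::vec prox_tv1d_cpp(const arma::vec& y, double lam) {
  arma::vec x(y.n_elem);
  tv1d_condat(y.memptr(), x.memptr(), y.n_elem, lam);
  return x;
}

// Row-wise proximal operator of
//   l1 * ||row||_1 + ltv * TV(row) + lgrp * ||row||_2
// applied to each row of V (features x times). The exact prox is the
// composition: TV prox, then soft-thresholding, then group L2 shrinkage.
// [[Rcpp::export(name = ".prox_fused_rows_cpp")]]
arma::mat prox_fused_rows_cpp(const arma::mat& v, double l1, double ltv,
                              double lgrp) {
  arma::mat out(v.n_rows, v.n_cols);
  arma::vec row(v.n_cols), tmp(v.n_cols);
  for (arma::uword j = 0; j < v.n_rows; ++j) {
    row = v.row(j).t();
    tv1d_condat(row.memptr(), tmp.memptr(), row.n_elem, ltv);
    if (l1 > 0.0) {
      for (arma::uword c = 0; c < tmp.n_elem; ++c) {
        double a = std::abs(tmp[c]) - l1;
        tmp[c] = a > 0.0 ? (tmp[c] > 0.0 ? a : -a) : 0.0;
      }
    }
    if (lgrp > 0.0) {
      double nrm = arma::norm(tmp, 2);
      double s = nrm > lgrp ? (1.0 - lgrp / nrm) : 0.0;
      tmp *= s;
    }
    out.row(j) = tmp.t();
  }
  return out;
}

// Scalar root of sum_g (b_g * nu / (a_g * nu + lam))^2 = nu^2 for nu > 0,
// used by the group update; caller guarantees ||b||_2 > lam.
static double group_root(const arma::vec& a, const arma::vec& b, double lam) {
  double hi = 0.0;
  for (arma::uword g = 0; g < a.n_elem; ++g) {
    if (a[g] > 0.0) hi += (b[g] / a[g]) * (b[g] / a[g]);
  }
  hi = std::sqrt(hi) + 1e-12;
  double lo = 0.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double s = 0.0;
    for (arma::uword g = 0; g < a.n_elem; ++g) {
      double d = a[g] * mid + lam;
      double t = b[g] * mid / d;
      s += t * t;
    }
    if (std::sqrt(s) > mid) lo = mid; else hi = mid;
    if (hi - lo < 1e-15 * (1.0 + hi)) break;
  }
  return 0.5 * (lo + hi);
}

// Block coordinate descent for the multi-task group LASSO
//   min_theta sum_g 0.5 ||x_g - Y_g theta_g||_2^2 + lam * sum_m ||theta_{m,.}||_2
// X: T x G expression profiles (columns = genes/tasks);
// Y: T x M x G cube of per-gene motif accessibility profiles;
// theta: M x G coefficients, group m = row m across all genes.
// [[Rcpp::export(name = ".mtg_bcd_cpp")]]
List mtg_bcd_cpp(const arma::mat& x, const arma::cube& y, double lam,
                 const arma::mat& theta0, int max_sweeps, double tol) {
  const arma::uword T = x.n_rows, G = x.n_cols, M = y.n_cols;
  if (y.n_rows != T || y.n_slices != G)
    stop("dimension mismatch between X and Y");
  arma::mat theta = theta0;
  if (theta.n_rows != M || theta.n_cols != G)
    theta = arma::zeros<arma::mat>(M, G);

  // residuals and squared column norms
  arma::mat resid = x;
  for (arma::uword g = 0; g < G; ++g) {
    resid.col(g) -= y.slice(g) * theta.col(g);
  }
  arma::mat a(M, G);
  for (arma::uword g = 0; g < G; ++g) {
    for (arma::uword m = 0; m < M; ++m) {
      a(m, g) = arma::dot(y.slice(g).col(m), y.slice(g).col(m));
    }
  }
  auto objective = [&]() {
    double o = 0.5 * arma::accu(resid % resid);
    for (arma::uword m = 0; m < M; ++m) o += lam * arma::norm(theta.row(m), 2);
    return o;
  };

  std::vector<double> trace;
  trace.push_back(objective());
  bool converged = false;
  int sweeps = 0;
  arma::vec b(G), tnew(G);
  for (sweeps = 1; sweeps <= max_sweeps; ++sweeps) {
    double max_change = 0.0, max_theta = 0.0;
    for (arma::uword m = 0; m < M; ++m) {
      for (arma::uword g = 0; g < G; ++g) {
        b[g] = arma::dot(y.slice(g).col(m), resid.col(g)) + a(m, g) * theta(m, g);
      }
      double bnorm = arma::norm(b, 2);
      if (bnorm <= lam) {
        tnew.zeros();
      } else {
        double nu = group_root(a.row(m).t(), b, lam);
        for (arma::uword g = 0; g < G; ++g) {
          tnew[g] = b[g] / (a(m, g) + lam / nu);
        }
      }
      for (arma::uword g = 0; g < G; ++g) {
        double d = tnew[g] - theta(m, g);
        if (d != 0.0) {
          resid.col(g) -= y.slice(g).col(m) * d;
          theta(m, g) = tnew[g];
        }
        max_change = std::max(max_change, std::abs(d));
        max_theta = std::max(max_theta, std::abs(theta(m, g)));
      }
    }
    trace.push_back(objective());
    if (max_change <= tol * (1.0 + max_theta)) {
      converged = true;
      break;
    }
  }
  return List::create(_["theta"] = theta,
                      _["objective"] = trace.back(),
                      _["obj_trace"] = trace,
                      _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
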