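#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Cyclic block proximal (generalized gradient) descent for the penalized
// objectives
//   gaussian:  (1/2n) ||y - Xb||^2 + alpha*lam*||b||_1
//                                  + (1-alpha)*lam * sum_g pg ||b_g||_2
//   binomial:  (1/n) * neg-loglik(b0, b) + same penalty
// alpha = 1 with singleton blocks is plain coordinate descent (lasso);
// alpha = 0 is group lasso. Blocks are contiguous column ranges; the R
// caller reorders columns so each group is one block.

namespace {

inline double soft1(double z, double t) {
  double a = std::fabs(z) - t;
  return a > 0.0 ? std::copysign(a, z) : 0.0;
}

// prox of t*( l1*||.||_1 + l2*||.||_2 ): soft-threshold then group shrink
inline void prox_block(arma::vec& z, double l1, double l2) {
  if (l1 > 0.0) {
    for (arma::uword j = 0; j < z.n_elem; ++j) z[j] = soft1(z[j], l1);
  }
  if (l2 > 0.0) {
    double nz = arma::norm(z, 2);
    if (nz <= l2) z.zeros(); else z *= (1.0 - l2 / nz);
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List fit_path_engine(const arma::mat& X, const arma::vec& y,
                           const arma::ivec& bstart, const arma::ivec& bsize,
                           const arma::vec& bpen, double alpha,
                           const arma::vec& lambdas, int family,
                           bool fit_intercept, double b0_init,
                           double tol, int max_sweeps) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword B = bstart.n_elem, L = lambdas.n_elem;
  const double dn = static_cast<double>(n);

  // exact per-block Lipschitz constants of the smooth loss
  arma::vec lip(B, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    arma::uword s = bstart[b], e = s + bsize[b] - 1;
    if (bsize[b] == 1) {
      lip[b] = arma::dot(X.col(s), X.col(s)) / dn;
    } else {
      arma::mat G = X.cols(s, e).t() * X.cols(s, e) / dn;
      arma::vec ev;
      arma::eig_sym(ev, G);
      lip[b] = ev.max();
    }
    if (family == 1) lip[b] *= 0.25;  // logistic hessian bound
  }

  arma::vec beta(p, arma::fill::zeros);
  double b0 = b0_init;
  arma::vec r, eta, prob;
  bool prob_fresh = false;
  if (family == 0) r = y; else eta = arma::vec(n, arma::fill::value(b0));

  arma::mat coefs(p, L, arma::fill::zeros);
  arma::vec icpt(L, arma::fill::zeros);
  arma::ivec iters(L, arma::fill::zeros), conv(L, arma::fill::zeros);

  for (arma::uword li = 0; li < L; ++li) {
    double lam = lambdas[li];
    bool done = false;
    int sweep = 0;
    for (sweep = 1; sweep <= max_sweeps; ++sweep) {
      double maxdel = 0.0;
      if (family == 1 && fit_intercept) {
        prob = 1.0 / (1.0 + arma::exp(-eta));
        double d0 = 4.0 * arma::mean(y - prob);  // step 1/L, L = 1/4
        if (d0 != 0.0) {
          b0 += d0; eta += d0; maxdel = std::fabs(d0);
          prob_fresh = false;
        } else {
          prob_fresh = true;
        }
      }
      for (arma::uword b = 0; b < B; ++b) {
        if (lip[b] <= 1e-12) continue;  // constant-zero block stays at 0
        arma::uword s = bstart[b], e = s + bsize[b] - 1;
        arma::vec bg = beta.subvec(s, e);
        arma::vec grad;
        if (family == 0) {
          grad = -(X.cols(s, e).t() * r) / dn;
        } else {
          if (!prob_fresh) {
            prob = 1.0 / (1.0 + arma::exp(-eta));
            prob_fresh = true;
          }
          grad = -(X.cols(s, e).t() * (y - prob)) / dn;
        }
        double step = 1.0 / lip[b];
        arma::vec z = bg - step * grad;
        prox_block(z, alpha * lam * step, (1.0 - alpha) * lam * bpen[b] * step);
        arma::vec d = z - bg;
        double md = arma::abs(d).max();
        if (md > 0.0) {
          if (family == 0) {
            r -= X.cols(s, e) * d;
          } else {
            eta += X.cols(s, e) * d;
            prob_fresh = false;
          }
          beta.subvec(s, e) = z;
          if (md > maxdel) maxdel = md;
        }
      }
      if (family == 0 && sweep % 1000 == 0) r = y - X * beta;  // resync
      double scale = std::max(1.0, beta.n_elem ? arma::abs(beta).max() : 0.0);
      if (maxdel / scale < tol) { done = true; break; }
    }
    if (!beta.is_finite() || !std::isfinite(b0))
      Rcpp::stop("non-finite coefficients at lambda index %d (lambda = %g)",
                 static_cast<int>(li) + 1, lam);
    coefs.col(li) = beta;
    icpt[li] = b0;
    iters[li] = done ? sweep : max_sweeps;
    conv[li] = done ? 1 : 0;
  }

  return Rcpp::List::create(Rcpp::Named("beta") = coefs,
                            Rcpp::Named("a0") = icpt,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("converged") = conv);
}
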