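#' Smallest penalty that zeroes out the whole model
#'
#' Computes the entry point of the regularization path: the smallest lambda
#' at which the all-zero coefficient vector satisfies the stationarity
#' conditions of the chosen objective. With `c_g = X_g' r0 / n` (r0 the
#' null-model residual):
#' lasso `max_j |c_j|`; group lasso `max_g ||c_g||_2 / p_g`; sparse group
#' lasso the per-group root of `||S(c_g, alpha*lambda)||_2 =
#' (1-alpha)*lambda*p_g` found by bisection, maximized over groups.
#'
#' @param data A [pl_data()] object.
#' @param groups A [group_structure()] (or group label vector).
#' @param method `"lasso"`, `"grouplasso"`, or `"sgl"`.
#' @param alpha Sparse-group mixing weight; `alpha = 1` / `alpha = 0` fall
#'   back to the lasso / group-lasso formulas.
#' @param standardize,intercept Match the transformation that [pl_fit()] will
#'   apply, so the value heads the same path.
#' @return A single nonnegative number.
#' @export
lambda_max <- function(data, groups, method = c("lasso", "grouplasso", "sgl"),
                       alpha = 0.95, standardize = TRUE, intercept = TRUE) {
  method <- match.arg(method)
  groups <- group_structure(groups)
  check_group_dims(groups, data$p)
  prep <- prepare_design(data, standardize = standardize,
                         intercept = intercept)
  lambda_max_std(prep$x, null_residual(prep), data$n, groups,
                 effective_alpha(method, alpha))
}

# null-model residual on the prepared scale
null_residual <- function(prep) {
  if (prep$family == "gaussian") prep$y
  else prep$y - mean(prep$y)  # p-bar = mean(y) at the null intercept
}

lambda_max_std <- function(xs, r0, n, groups, a) {
  # relative safety margin so the all-zero solution survives floating-point
  # ties in the solver's prox-threshold comparison at lambda = lambda_max
  eps <- 1 + 1e-10
  cg <- drop(crossprod(xs, r0)) / n
  if (a >= 1) return(max(abs(cg), 0) * eps)
  per_group <- vapply(groups$groups, function(g) {
    idx <- which(groups$group_of == g)
    c_g <- cg[idx]
    pg <- groups$weights[[g]]
    if (a <= 0) return(sqrt(sum(c_g^2)) / pg)
    # bisection for ||S(c_g, a*lam)|| = (1-a)*lam*pg (LHS dec., RHS inc.)
    f <- function(lam) sqrt(sum(pmax(abs(c_g) - a * lam, 0)^2)) -
      (1 - a) * lam * pg
    hi <- max(abs(c_g)) / a
    if (hi <= 0) return(0)
    lo <- 0
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    hi
  }, numeric(1))
  max(per_group, 0) * eps
}

#' Log-spaced decreasing lambda grid
#'
#' @param lam_max Positive top of the path.
#' @param n_lambda Number of grid points (at least 2).
#' @param min_ratio Ratio of the smallest to the largest lambda, in (0, 1).
#' @return Strictly decreasing vector of length `n_lambda` from `lam_max`
#'   down to `min_ratio * lam_max`.
#' @export
#' @examples
#' make_lambda_path(1, 3, 0.01)  # 1, 0.1, 0.01
make_lambda_path <- function(lam_max, n_lambda = 100, min_ratio = 1e-4) {
  if (!is.numeric(lam_max) || length(lam_max) != 1 || is.na(lam_max) ||
      lam_max <= 0)
    stop("'lam_max' must be a single positive number")
  if (n_lambda < 2) stop("'n_lambda' must be at least 2")
  if (min_ratio <= 0 || min_ratio >= 1)
    stop("'min_ratio' must be in (0, 1)")
  exp(seq(log(lam_max), log(min_ratio * lam_max), length.out = n_lambda))
}
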