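#' Subgradient (KKT) optimality check
#'
#' Measures how far a candidate coefficient vector is from satisfying the
#' stationarity conditions of the penalized objective, in the metric of the
#' gradient. With `g = grad(loss)` at `(intercept, beta)` and effective l1
#' weight `a` (lasso 1, group lasso 0, sparse group `alpha`):
#' \itemize{
#' \item zero group: `max(0, ||S(g_g, a*lambda)||_2 - (1-a)*lambda*p_g)`
#'   (S = elementwise soft-threshold);
#' \item nonzero coordinate in an active group:
#'   `|g_j + a*lambda*sign(beta_j) + (1-a)*lambda*p_g*beta_j/||beta_g||_2|`;
#' \item zero coordinate in an active group: `max(0, |g_j| - a*lambda)`.
#' }
#' The returned value is the maximum over all conditions; an exact minimizer
#' gives 0.
#'
#' @param data A [pl_data()] object, on the same scale the coefficients refer
#'   to.
#' @param groups A [group_structure()] (or group label vector).
#' @param beta Candidate coefficients (length p).
#' @param spec A [penalty_spec()].
#' @param intercept Intercept used when computing residuals (default 0).
#' @return Largest stationarity violation (nonnegative scalar).
#' @export
check_optimality <- function(data, groups, beta, spec, intercept = 0) {
  groups <- group_structure(groups)
  check_group_dims(groups, data$p)
  if (length(beta) != data$p) stop("'beta' has wrong length")
  a <- effective_alpha(spec$method, spec$alpha)
  lam <- spec$lambda
  eta <- drop(data$x %*% beta) + intercept
  resid <- if (data$family == "gaussian") data$y - eta else data$y - plogis(eta)
  grad <- -drop(crossprod(data$x, resid)) / data$n

  viol <- 0
  for (g in groups$groups) {
    idx <- which(groups$group_of == g)
    bg <- beta[idx]; gg <- grad[idx]
    pg <- groups$weights[[g]]
    if (all(bg == 0)) {
      v <- max(0, sqrt(sum(pmax(abs(gg) - a * lam, 0)^2)) -
                 (1 - a) * lam * pg)
    } else {
      nb <- sqrt(sum(bg^2))
      nz <- bg != 0
      v_nz <- abs(gg[nz] + a * lam * sign(bg[nz]) +
                    (1 - a) * lam * pg * bg[nz] / nb)
      v_z <- if (any(!nz)) pmax(abs(gg[!nz]) - a * lam, 0) else 0
      v <- max(v_nz, v_z)
    }
    viol <- max(viol, v)
  }
  viol
}
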