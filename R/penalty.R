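#' Scalar soft-thresholding operator
#'
#' `S(z, t) = sign(z) * max(|z| - t, 0)`, the proximal operator of `t*|.|`.
#' Vectorized over `z`.
#'
#' @param z Numeric vector.
#' @param t Threshold, a single nonnegative number.
#' @return Numeric vector of the same length as `z`.
#' @export
#' @examples
#' soft_threshold(c(3, -0.5, -3), 1)  # 2, 0, -2
soft_threshold <- function(z, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("'t' must be a single nonnegative number")
  sign(z) * pmax(abs(z) - t, 0)
}

#' Group (vector) soft-thresholding operator
#'
#' `max(1 - t / ||v||_2, 0) * v`, the proximal operator of `t*||.||_2`; the
#' whole vector collapses to zero when its Euclidean norm is at most `t`.
#'
#' @param v Numeric vector.
#' @param t Threshold, a single nonnegative number.
#' @return Numeric vector of the same length as `v`, a nonnegative scalar
#'   multiple of `v`.
#' @export
#' @examples
#' group_soft_threshold(c(3, 4), 2.5)  # scaled by 1 - 2.5/5
group_soft_threshold <- function(v, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("'t' must be a single nonnegative number")
  nv <- sqrt(sum(v^2))
  if (nv <= t) return(rep(0, length(v)))
  (1 - t / nv) * v
}

#' Penalty specification
#'
#' @param method One of `"lasso"`, `"grouplasso"`, `"sgl"` (sparse group
#'   lasso).
#' @param lambda Penalty strength, nonnegative.
#' @param alpha Mixing weight in \[0, 1\] between the l1 part (`alpha`) and the
#'   group part (`1 - alpha`); used only by `"sgl"`. `alpha = 1` recovers the
#'   lasso penalty and `alpha = 0` the group-lasso penalty.
#' @return Object of class `pl_penalty`.
#' @export
penalty_spec <- function(method = c("lasso", "grouplasso", "sgl"),
                         lambda, alpha = 0.95) {
  method <- match.arg(method)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a single nonnegative number")
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("'alpha' must be in [0, 1]")
  structure(list(method = method, lambda = lambda, alpha = alpha),
            class = "pl_penalty")
}

# effective l1 mixing weight implied by the method
effective_alpha <- function(method, alpha) {
  switch(method, lasso = 1, grouplasso = 0, sgl = alpha,
         stop("unknown method '", method, "'"))
}

#' Penalty value of a coefficient vector
#'
#' Lasso: `lambda * ||beta||_1`. Group lasso:
#' `lambda * sum_g p_g ||beta_g||_2`. Sparse group lasso:
#' `alpha*lambda*||beta||_1 + (1-alpha)*lambda * sum_g p_g ||beta_g||_2`.
#'
#' @param beta Coefficient vector (length p).
#' @param groups A [group_structure()] object (or group label vector).
#' @param spec A [penalty_spec()].
#' @return A single nonnegative number.
#' @export
penalty_value <- function(beta, groups, spec) {
  groups <- group_structure(groups)
  check_group_dims(groups, length(beta))
  a <- effective_alpha(spec$method, spec$alpha)
  l1 <- sum(abs(beta))
  l2 <- sum(vapply(groups$groups, function(g) {
    groups$weights[[g]] * sqrt(sum(beta[groups$group_of == g]^2))
  }, numeric(1)))
  spec$lambda * (a * l1 + (1 - a) * l2)
}

# smooth loss under the package's scaling convention:
# gaussian  (1/2n)||y - b0 - X beta||^2
# binomial  (1/n) * negative bernoulli log-likelihood, probabilities clamped
model_loss <- function(data, beta, intercept = 0) {
  eta <- drop(data$x %*% beta) + intercept
  if (data$family == "gaussian") {
    sum((data$y - eta)^2) / (2 * data$n)
  } else {
    p <- plogis(eta)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -mean(data$y * log(p) + (1 - data$y) * log(1 - p))
  }
}

#' Penalized objective value
#'
#' Evaluates `loss(beta) + penalty(beta)` for a coefficient vector under the
#' package's scaling convention: squared-error loss divided by `2n`
#' (gaussian) or negative log-likelihood divided by `n` (binomial). Dividing
#' by the sample size keeps lambda grids comparable across n; objectives
#' written without the factor differ from these values by the constant `2n`
#' (or `n`).
#'
#' @param data A [pl_data()] object.
#' @param groups A [group_structure()] object (or group label vector).
#' @param beta Coefficient vector of length `data$p`.
#' @param spec A [penalty_spec()].
#' @param intercept Intercept (default 0; the intercept is never penalized).
#' @return A single number.
#' @export
#' @examples
#' d <- pl_data(matrix(rnorm(40), 10, 4), rnorm(10))
#' g <- group_structure(c(1, 1, 2, 2))
#' objective_value(d, g, rep(0, 4), penalty_spec("lasso", 0.5))
objective_value <- function(data, groups, beta, spec, intercept = 0) {
  if (!inherits(data, "pl_data")) stop("'data' must be a pl_data object")
  if (!inherits(spec, "pl_penalty")) stop("'spec' must be a penalty_spec()")
  if (length(beta) != data$p)
    stop("length of 'beta' (", length(beta),
         ") does not match number of predictors (", data$p, ")")
  groups <- group_structure(groups)
  check_group_dims(groups, data$p)
  model_loss(data, beta, intercept) + penalty_value(beta, groups, spec)
}
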