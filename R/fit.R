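# center/scale the design per the fitting options; gaussian y is centered
# when an intercept is requested. Returns the transformed problem plus the
# bookkeeping needed to map coefficients back to the original scale.
prepare_design <- function(data, standardize = TRUE, intercept = TRUE) {
  x <- data$x
  centers <- if (intercept) colMeans(x) else rep(0, data$p)
  xc <- sweep(x, 2, centers, "-")
  colsd <- sqrt(colMeans(sweep(x, 2, colMeans(x), "-")^2))
  constant <- colsd == 0
  if (standardize) {
    if (any(constant))
      warning("constant columns get coefficient 0: ",
              paste(data$predictor_names[constant], collapse = ", "))
    scales <- ifelse(constant, 1, colsd)
    xc <- sweep(xc, 2, scales, "/")
  } else {
    scales <- rep(1, data$p)
  }
  if (data$family == "gaussian") {
    ymean <- if (intercept) mean(data$y) else 0
    yt <- data$y - ymean
    b0_init <- 0
  } else {
    ymean <- 0
    yt <- data$y
    b0_init <- if (intercept) qlogis(mean(data$y)) else 0
  }
  list(x = xc, y = yt, family = data$family, centers = centers,
       scales = scales, ymean = ymean, b0_init = b0_init,
       constant = constant)
}

#' Fit a lasso, group lasso, or sparse group lasso regularization path
#'
#' Minimizes, over a decreasing lambda grid with warm starts,
#' `loss(b0, beta) + penalty(beta)` where the loss is `(1/2n)||y - b0 -
#' X beta||^2` (gaussian) or the mean logistic negative log-likelihood
#' (binomial), and the penalty is `lambda*||beta||_1` (lasso),
#' `lambda * sum_g p_g ||beta_g||_2` (group lasso), or their convex
#' combination weighted by `alpha` (sparse group lasso). The solver is
#' deterministic cyclic block proximal descent: each block takes a gradient
#' step on the smooth loss at the exact block Lipschitz step size, followed
#' by elementwise soft-thresholding (l1 part) and block soft-thresholding
#' (group part). With `alpha = 1` blocks reduce to single coordinates and the
#' update is classical coordinate descent.
#'
#' @param x Design matrix (n x p) or a [pl_data()] object (then `y`/`family`
#'   are taken from it).
#' @param y Response vector; ignored when `x` is a `pl_data`.
#' @param group Group labels (length p), a [group_structure()], or `NULL`
#'   (every predictor its own group; required form for `method = "lasso"`
#'   charts but the lasso fit itself ignores grouping).
#' @param method `"lasso"`, `"grouplasso"`, or `"sgl"`.
#' @param family `"gaussian"`, `"binomial"`, or `NULL` to infer.
#' @param alpha Sparse-group mixing weight in \[0, 1\] (default 0.95, i.e.
#'   mostly l1). `alpha = 1` and `alpha = 0` are routed to the lasso and
#'   group-lasso code paths, which solve the identical objectives.
#' @param lambda Optional user lambda sequence (sorted decreasing
#'   internally). Default: `nlambda` log-spaced values from
#'   [lambda_max()] down to `lambda_min_ratio` times it.
#' @param nlambda,lambda_min_ratio Path controls. `lambda_min_ratio` defaults
#'   to `1e-2` when `p > n`, else `1e-4`.
#' @param group_weights Optional per-group penalty weights `p_g`
#'   (default `sqrt(size)`).
#' @param standardize Center and unit-variance-scale columns before fitting
#'   (coefficients are reported on the original scale). Constant columns get
#'   coefficient 0 with a warning.
#' @param intercept Fit an unpenalized intercept.
#' @param tol Convergence tolerance: largest coefficient change in a sweep,
#'   relative to `max(1, max|beta|)`.
#' @param max_sweeps Sweep cap per lambda; hitting it flags
#'   `converged = FALSE` with a warning.
#'
#' @return Object of class `pl_fit` with elements `lambda`, `beta` (p x L,
#'   original scale), `a0` (intercepts), `beta_std`/`a0_std` (the scale the
#'   solver worked on), `df` (nonzero count per lambda), `n_iter`,
#'   `converged`, `method`, `family`, `alpha`, `groups`, and the
#'   centering/scaling applied.
#' @seealso [cv_pl_fit()], [check_optimality()], [chart_layout()]
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n = 60, n_groups = 4, group_size = 3,
#'                                    n_active = 2, seed = 1))
#' fit <- pl_fit(sim$data, group = sim$groups, method = "grouplasso")
#' fit
pl_fit <- function(x, y = NULL, group = NULL,
                   method = c("lasso", "grouplasso", "sgl"),
                   family = NULL, alpha = 0.95,
                   lambda = NULL, nlambda = 100, lambda_min_ratio = NULL,
                   group_weights = NULL,
                   standardize = TRUE, intercept = TRUE,
                   tol = 1e-7, max_sweeps = 100000L) {
  method <- match.arg(method)
  data <- if (inherits(x, "pl_data")) x else pl_data(x, y, family = family)
  if (is.null(group)) {
    if (method != "lasso")
      stop("'group' is required for method '", method, "'")
    group <- data$predictor_names
  }
  groups <- group_structure(group, weights = group_weights)
  check_group_dims(groups, data$p)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("'alpha' must be in [0, 1]")
  a <- effective_alpha(method, alpha)

  prep <- prepare_design(data, standardize = standardize,
                         intercept = intercept)
  n <- data$n; p <- data$p

  if (is.null(lambda)) {
    lmax <- lambda_max_std(prep$x, null_residual(prep), n, groups, a)
    if (lmax <= 0) lmax <- 1e-3  # degenerate: y orthogonal to all columns
    if (is.null(lambda_min_ratio))
      lambda_min_ratio <-
        if (p > n || data$family == "binomial") 1e-2 else 1e-4
    lambda <- make_lambda_path(lmax, nlambda, lambda_min_ratio)
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
    if (any(lambda < 0) || anyNA(lambda))
      stop("'lambda' values must be nonnegative")
  }

  # contiguous blocks: singletons for the l1-only path, else one per group
  if (a >= 1) {
    ord <- seq_len(p)
    bstart <- seq_len(p); bsize <- rep(1L, p); bpen <- rep(1, p)
  } else {
    ord <- order(match(groups$group_of, groups$groups))
    bsize <- as.integer(groups$sizes)
    bstart <- cumsum(c(1L, bsize[-length(bsize)]))
    bpen <- as.numeric(groups$weights)
  }

  eng <- fit_path_engine(prep$x[, ord, drop = FALSE], prep$y,
                         as.integer(bstart - 1L), as.integer(bsize), bpen,
                         a, lambda, if (data$family == "gaussian") 0L else 1L,
                         intercept, prep$b0_init, tol,
                         as.integer(max_sweeps))

  L <- length(lambda)
  beta_std <- matrix(0, p, L)
  beta_std[ord, ] <- eng$beta
  beta_std[prep$constant, ] <- 0
  beta <- beta_std / prep$scales
  a0_std <- as.numeric(eng$a0)
  a0 <- if (data$family == "gaussian") {
    prep$ymean - colSums(beta * prep$centers)
  } else {
    a0_std - colSums(beta * prep$centers)
  }
  dimnames(beta) <- dimnames(beta_std) <-
    list(data$predictor_names, paste0("l", seq_len(L)))
  converged <- as.logical(eng$converged)
  if (!all(converged))
    warning("solver hit the sweep cap at ", sum(!converged),
            " lambda value(s); results there may be inexact")

  structure(list(lambda = lambda, beta = beta, a0 = a0,
                 beta_std = beta_std, a0_std = a0_std,
                 df = colSums(beta != 0),
                 n_iter = as.integer(eng$iters), converged = converged,
                 method = method, family = data$family,
                 alpha = if (method == "sgl") alpha else NA_real_,
                 groups = groups, predictor_names = data$predictor_names,
                 n = n, p = p,
                 center = prep$centers, scale = prep$scales,
                 standardize = standardize, intercept = intercept,
                 tol = tol, call = match.call()),
            class = "pl_fit")
}

#' @export
print.pl_fit <- function(x, ...) {
  cat(sprintf("pl_fit: %s (%s), %d lambdas in [%.4g, %.4g]\n",
              x$method, x$family, length(x$lambda),
              min(x$lambda), max(x$lambda)))
  cat(sprintf("  %d samples, %d predictors in %d groups; df range %d-%d\n",
              x$n, x$p, length(x$groups$groups),
              min(x$df), max(x$df)))
  invisible(x)
}

# resolve a lambda/index pair to one path position
resolve_index <- function(object, index = NULL, lambda = NULL) {
  if (!is.null(index)) {
    if (index < 1 || index > length(object$lambda))
      stop("path index out of range")
    return(as.integer(index))
  }
  if (is.null(lambda)) return(length(object$lambda))
  which.min(abs(object$lambda - lambda))
}

#' Extract coefficients from a fitted path
#'
#' @param object A `pl_fit`.
#' @param index Path position (1 = largest lambda); default the last.
#' @param lambda Alternatively, a lambda value (nearest grid point used).
#' @param scale `"original"` (default) or `"standardized"` (the scale the
#'   solver worked on).
#' @param ... Unused.
#' @return Named vector `c("(Intercept)", predictors)`.
#' @export
coef.pl_fit <- function(object, index = NULL, lambda = NULL,
                        scale = c("original", "standardized"), ...) {
  scale <- match.arg(scale)
  i <- resolve_index(object, index, lambda)
  b <- if (scale == "original") object$beta[, i] else object$beta_std[, i]
  a0 <- if (scale == "original") object$a0[i] else object$a0_std[i]
  stats::setNames(c(a0, b), c("(Intercept)", object$predictor_names))
}

#' Predict from a fitted path
#'
#' @param object A `pl_fit`.
#' @param newx Matrix of new observations (original scale).
#' @param index,lambda Path position, as in [coef.pl_fit()].
#' @param type `"link"` (linear predictor) or `"response"` (probabilities for
#'   binomial; identical to link for gaussian).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pl_fit <- function(object, newx, index = NULL, lambda = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  i <- resolve_index(object, index, lambda)
  eta <- drop(as.matrix(newx) %*% object$beta[, i]) + object$a0[i]
  if (type == "response" && object$family == "binomial") plogis(eta) else eta
}

# group labels with at least one nonzero coefficient at a path position
selected_groups <- function(fit, index = NULL, lambda = NULL) {
  i <- resolve_index(fit, index, lambda)
  b <- fit$beta[, i]
  g <- fit$groups
  g$groups[vapply(g$groups,
                  function(gr) any(b[g$group_of == gr] != 0), logical(1))]
}
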