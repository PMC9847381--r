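#' Deterministic k-fold assignment
#'
#' Assigns each of n samples to one of k folds, balanced to within one
#' sample, reproducibly from `seed`. With `strata` (e.g. a binary response),
#' the balance guarantee holds within every stratum, so class proportions are
#' matched across folds up to rounding.
#'
#' @param n Number of samples.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed; identical `(n, k, seed, strata)` gives an
#'   identical assignment.
#' @param strata Optional length-n labels for stratified assignment.
#' @return Integer vector of fold ids in `1..k`.
#' @export
#' @examples
#' table(make_folds(10, 3, seed = 1))
make_folds <- function(n, k, seed = 1, strata = NULL) {
  if (k < 2) stop("'k' must be at least 2")
  if (k > n) stop("'k' (", k, ") cannot exceed n (", n, ")")
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(strata)) {
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      strata <- as.character(strata)
      if (length(strata) != n) stop("'strata' must have length n")
      for (s in unique(strata)) {
        idx <- which(strata == s)
        if (length(idx) < k)
          warning("stratum '", s, "' has fewer samples (", length(idx),
                  ") than folds (", k, "); balance degraded")
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
    fold
  })
}

# held-out loss per lambda: MSE (gaussian) or mean binomial deviance
holdout_loss <- function(fit, xte, yte) {
  eta <- sweep(as.matrix(xte) %*% fit$beta, 2, fit$a0, "+")
  if (fit$family == "gaussian") {
    colMeans((yte - eta)^2)
  } else {
    p <- plogis(eta)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    colMeans(-2 * (yte * log(p) + (1 - yte) * log(1 - p)))
  }
}

#' Cross-validated regularization path
#'
#' Fits the full-data path to fix a lambda grid, then refits on each fold
#' complement and evaluates the held-out loss (squared error for gaussian,
#' binomial deviance for binomial) at every lambda. `cvm` is the mean of the
#' k per-fold mean losses and `cvsd` their standard deviation divided by
#' `sqrt(k)` (fold-level standard error). Folds are stratified by class
#' automatically for the binomial family.
#'
#' @inheritParams pl_fit
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment; the whole result is a
#'   deterministic function of the inputs and this seed.
#' @param foldid Optional user fold assignment overriding `k`/`seed`.
#' @param ... Further arguments passed to [pl_fit()].
#' @return Object of class `pl_cv`: `lambda`, `cvm`, `cvsd`, `index_min`,
#'   `index_1se`, `lambda.min`, `lambda.1se`, `nzero`, `foldid`, `k`, `seed`,
#'   and `fit`, the full-data `pl_fit`.
#' @seealso [select_lambda()], [chart_layout()]
#' @export
cv_pl_fit <- function(x, y = NULL, group = NULL,
                      method = c("lasso", "grouplasso", "sgl"),
                      family = NULL, alpha = 0.95,
                      k = 10, seed = 1, foldid = NULL, lambda = NULL, ...) {
  method <- match.arg(method)
  data <- if (inherits(x, "pl_data")) x else pl_data(x, y, family = family)
  fit <- pl_fit(data, group = group, method = method, alpha = alpha,
                lambda = lambda, ...)
  lambda <- fit$lambda

  if (is.null(foldid)) {
    strata <- if (data$family == "binomial") data$y else NULL
    foldid <- make_folds(data$n, k, seed = seed, strata = strata)
  } else {
    if (length(foldid) != data$n) stop("'foldid' must have length n")
    k <- length(unique(foldid))
  }

  fold_loss <- matrix(NA_real_, k, length(lambda))
  for (f in seq_len(k)) {
    tr <- foldid != f
    ytr <- data$y[tr]
    if (data$family == "binomial" && length(unique(ytr)) < 2)
      stop("fold ", f, " training set lost an entire class; ",
           "use stratified folds")
    fold_fit <- pl_fit(data$x[tr, , drop = FALSE], ytr, group = group,
                       method = method, family = data$family, alpha = alpha,
                       lambda = lambda, ...)
    fold_loss[f, ] <- holdout_loss(fold_fit,
                                   data$x[!tr, , drop = FALSE],
                                   data$y[!tr])
  }
  cvm <- colMeans(fold_loss)
  cvsd <- apply(fold_loss, 2, sd) / sqrt(k)

  index_min <- select_index(lambda, cvm, cvsd, "min")
  index_1se <- select_index(lambda, cvm, cvsd, "1se")

  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 index_min = index_min, index_1se = index_1se,
                 lambda.min = lambda[index_min],
                 lambda.1se = lambda[index_1se],
                 nzero = fit$df, fold_loss = fold_loss,
                 foldid = foldid, k = k, seed = seed,
                 method = method, family = data$family, fit = fit),
            class = "pl_cv")
}

# shared selection logic; lambda assumed decreasing
select_index <- function(lambda, cvm, cvsd, rule) {
  imin <- which(cvm == min(cvm))[1]  # ties -> largest lambda
  if (rule == "min") return(imin)
  band <- cvm[imin] + cvsd[imin]
  which(cvm <= band)[1]  # largest lambda within one SE of the minimum
}

#' Pick a lambda index from a cross-validation result
#'
#' `"min"` chooses the lambda minimizing the CV loss (ties broken toward the
#' larger, sparser lambda). `"1se"` chooses the largest lambda whose CV loss
#' is within one standard error of that minimum; it selects fewer variables.
#'
#' @param cv A `pl_cv` object.
#' @param rule `"min"` or `"1se"`.
#' @return Integer index into `cv$lambda`.
#' @export
select_lambda <- function(cv, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  select_index(cv$lambda, cv$cvm, cv$cvsd, rule)
}

#' @export
print.pl_cv <- function(x, ...) {
  cat(sprintf("pl_cv: %s (%s), %d-fold, seed %s\n",
              x$method, x$family, x$k, format(x$seed)))
  cat(sprintf("  lambda.min = %.5g (cvm %.5g, %d nonzero)\n",
              x$lambda.min, x$cvm[x$index_min], x$nzero[x$index_min]))
  cat(sprintf("  lambda.1se = %.5g (cvm %.5g, %d nonzero)\n",
              x$lambda.1se, x$cvm[x$index_1se], x$nzero[x$index_1se]))
  invisible(x)
}
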