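# Independent oracle: full-vector accelerated proximal gradient (FISTA with
# function-value restart) on the identical objective, written without any of
# the package's solver code. Used to certify the block-descent solutions.

oracle_objective <- function(x, y, beta, b0, group, weights, alpha, lambda,
                             family) {
  n <- nrow(x)
  eta <- drop(x %*% beta) + b0
  loss <- if (family == "gaussian") {
    sum((y - eta)^2) / (2 * n)
  } else {
    mean(log(1 + exp(-(2 * y - 1) * eta)))
  }
  gl <- split(seq_along(beta), factor(group, levels = unique(group)))
  pen <- alpha * sum(abs(beta)) +
    (1 - alpha) * sum(mapply(function(idx, w) w * sqrt(sum(beta[idx]^2)),
                             gl, weights[unique(group)]))
  loss + lambda * pen
}

fista_solve <- function(x, y, group, weights, alpha, lambda,
                        family = "gaussian", intercept = FALSE,
                        max_iter = 100000, tol = 1e-13) {
  n <- nrow(x); p <- ncol(x)
  xa <- if (intercept) cbind(1, x) else x
  off <- if (intercept) 1L else 0L
  lip <- max(eigen(crossprod(xa) / n, symmetric = TRUE,
                   only.values = TRUE)$values)
  if (family == "binomial") lip <- lip / 4
  gl <- split(seq_len(p), factor(group, levels = unique(group)))
  wg <- weights[unique(group)]

  grad_fun <- function(b) {
    eta <- drop(xa %*% b)
    r <- if (family == "gaussian") y - eta else y - plogis(eta)
    -drop(crossprod(xa, r)) / n
  }
  obj <- function(b) {
    oracle_objective(x, y, b[(off + 1):(off + p)],
                     if (intercept) b[1] else 0,
                     group, weights, alpha, lambda, family)
  }
  prox <- function(b, step) {
    bb <- b[(off + 1):(off + p)]
    if (alpha > 0) bb <- sign(bb) * pmax(abs(bb) - alpha * lambda * step, 0)
    if (alpha < 1) {
      for (k in seq_along(gl)) {
        idx <- gl[[k]]
        t2 <- (1 - alpha) * lambda * wg[k] * step
        nb <- sqrt(sum(bb[idx]^2))
        bb[idx] <- if (nb <= t2) 0 else (1 - t2 / nb) * bb[idx]
      }
    }
    b[(off + 1):(off + p)] <- bb
    b
  }

  b <- v <- rep(0, p + off)
  tk <- 1
  f_prev <- obj(b)
  stall <- 0
  for (it in seq_len(max_iter)) {
    b_new <- prox(v - grad_fun(v) / lip, 1 / lip)
    f_new <- obj(b_new)
    if (f_new > f_prev) {      # restart momentum
      v <- b
      tk <- 1
      b_new <- prox(v - grad_fun(v) / lip, 1 / lip)
      f_new <- obj(b_new)
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    v <- b_new + ((tk - 1) / t_new) * (b_new - b)
    stall <- if (abs(f_prev - f_new) < tol * (1 + abs(f_new))) stall + 1
             else 0
    b <- b_new; tk <- t_new; f_prev <- f_new
    if (stall >= 20) break
  }
  list(beta = b[(off + 1):(off + p)],
       intercept = if (intercept) b[1] else 0,
       value = f_prev, iterations = it)
}

# fit one lambda with the package and compare objectives against the oracle;
# returns c(package objective, oracle objective, kkt violation)
solver_vs_oracle <- function(inst, method, lambda_frac, alpha = 0.5) {
  data <- inst$data; groups <- inst$groups
  a <- switch(method, lasso = 1, grouplasso = 0, sgl = alpha)
  use_int <- data$family == "binomial"
  lmax <- polarlasso::lambda_max(data, groups, method = method,
                                 alpha = alpha, standardize = FALSE,
                                 intercept = use_int)
  lam <- lambda_frac * lmax
  fit <- polarlasso::pl_fit(data$x, data$y, group = groups, method = method,
                            family = data$family, alpha = alpha,
                            lambda = c(lmax, lam), standardize = FALSE,
                            intercept = use_int, tol = 1e-9)
  spec <- polarlasso::penalty_spec(method, lam, alpha)
  b <- fit$beta[, 2]
  f_pkg <- polarlasso::objective_value(data, groups, b, spec,
                                       intercept = fit$a0[2])
  orc <- fista_solve(data$x, data$y, groups$group_of, groups$weights,
                     a, lam, family = data$family, intercept = use_int)
  kkt <- polarlasso::check_optimality(data, groups, b, spec,
                                      intercept = fit$a0[2])
  c(pkg = f_pkg, oracle = orc$value, kkt = kkt)
}
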