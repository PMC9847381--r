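test_that("lambda path is log-spaced and strictly decreasing", {
  expect_equal(make_lambda_path(1.0, 3, 0.01), c(1.0, 0.1, 0.01))
  p <- make_lambda_path(10, 100, 1e-3)
  expect_length(p, 100)
  expect_equal(p[1], 10)
  expect_equal(p[100], 0.01)
  expect_true(all(diff(p) < 0))
  expect_error(make_lambda_path(-1, 10, 0.1), "positive")
  expect_error(make_lambda_path(1, 1, 0.1), "at least 2")
})

test_that("lambda_max marks the boundary of the all-zero solution", {
  inst <- random_instance(11)
  d <- inst$data; g <- inst$groups
  for (m in c("lasso", "grouplasso", "sgl")) {
    lmax <- lambda_max(d, g, method = m, alpha = 0.5,
                       standardize = FALSE, intercept = FALSE)
    fit <- pl_fit(d$x, d$y, group = g, method = m, family = "gaussian",
                  alpha = 0.5, lambda = c(lmax, 0.5 * lmax),
                  standardize = FALSE, intercept = FALSE)
    expect_identical(unname(fit$beta[, 1]), rep(0, d$p))
    expect_gt(sum(fit$beta[, 2] != 0), 0)
    # zero solution is KKT-clean at lambda_max
    viol <- check_optimality(d, g, rep(0, d$p),
                             penalty_spec(m, lmax, 0.5))
    expect_lt(viol, 1e-10)
  }
  # sgl at alpha = 1 falls back to the lasso formula
  expect_equal(lambda_max(d, g, "sgl", alpha = 1, standardize = FALSE,
                          intercept = FALSE),
               lambda_max(d, g, "lasso", standardize = FALSE,
                          intercept = FALSE))
})

test_that("lambda_max is zero when the response is orthogonal to X", {
  x <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  colnames(x) <- c("a", "b")
  y <- c(1, 1, -1, -1)  # orthogonal to both columns
  d <- pl_data(x, y)
  g <- group_structure(c("g1", "g1"))
  for (m in c("lasso", "grouplasso"))
    expect_equal(lambda_max(d, g, m, standardize = FALSE,
                            intercept = FALSE), 0)
})

test_that("orthonormal-design lasso matches the soft-threshold closed form", {
  set.seed(21)
  n <- 40; p <- 8
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # X'X/n = I
  colnames(q) <- paste0("V", 1:p)
  y <- drop(q %*% c(2, -1.5, rep(0, p - 2))) + rnorm(n, sd = 0.3)
  lam <- 0.4
  fit <- pl_fit(q, y, method = "lasso", family = "gaussian",
                lambda = lam, standardize = FALSE, intercept = FALSE,
                tol = 1e-12)
  expected <- unname(soft_threshold(drop(crossprod(q, y)) / n, lam))
  expect_equal(unname(fit$beta[, 1]), expected, tolerance = 1e-8)
})

test_that("all methods reduce to unpenalized least squares at lambda = 0", {
  inst <- random_instance(31, n = 60, p = 10, G = 5)
  d <- inst$data; g <- inst$groups
  ols <- unname(coef(lm(d$y ~ d$x - 1)))
  for (m in c("lasso", "grouplasso", "sgl")) {
    lmax <- lambda_max(d, g, m, standardize = FALSE, intercept = FALSE)
    fit <- pl_fit(d$x, d$y, group = g, method = m, family = "gaussian",
                  lambda = c(lmax, lmax / 10, 0), standardize = FALSE,
                  intercept = FALSE, tol = 1e-10)
    expect_equal(unname(fit$beta[, 3]), ols, tolerance = 1e-6)
  }
})

test_that("sparse group lasso at alpha 1 / 0 reproduces lasso / group lasso", {
  for (family in c("gaussian", "binomial")) {
    inst <- random_instance(41, family = family)
    d <- inst$data; g <- inst$groups
    f_sgl1 <- pl_fit(d$x, d$y, group = g, method = "sgl", alpha = 1,
                     family = family, nlambda = 30)
    f_las <- pl_fit(d$x, d$y, group = g, method = "lasso",
                    family = family, lambda = f_sgl1$lambda)
    expect_equal(f_sgl1$beta, f_las$beta, tolerance = 1e-8)
    f_sgl0 <- pl_fit(d$x, d$y, group = g, method = "sgl", alpha = 0,
                     family = family, nlambda = 30)
    f_grp <- pl_fit(d$x, d$y, group = g, method = "grouplasso",
                    family = family, lambda = f_sgl0$lambda)
    expect_equal(f_sgl0$beta, f_grp$beta, tolerance = 1e-8)
  }
})

test_that("lasso path agrees with glmnet on both families", {
  skip_if_not_installed("glmnet")
  for (family in c("gaussian", "binomial")) {
    inst <- random_instance(51, family = family)
    d <- inst$data
    use_int <- family == "binomial"
    lmax <- lambda_max(d, group_structure(colnames(d$x)), "lasso",
                       standardize = FALSE, intercept = use_int)
    lams <- make_lambda_path(lmax, 20, 0.05)
    fit <- pl_fit(d$x, d$y, method = "lasso", family = family,
                  lambda = lams, standardize = FALSE, intercept = use_int,
                  tol = 1e-10)
    gn <- glmnet::glmnet(d$x, d$y, family = family, lambda = lams,
                         standardize = FALSE, intercept = use_int,
                         thresh = 1e-14)
    expect_equal(unname(as.matrix(gn$beta)), unname(fit$beta),
                 tolerance = 1e-4)
  }
})

test_that("returned solutions satisfy the KKT certificate and beat a
           perturbed copy", {
  inst <- random_instance(61)
  d <- inst$data; g <- inst$groups
  for (m in c("lasso", "grouplasso", "sgl")) {
    lmax <- lambda_max(d, g, m, alpha = 0.5, standardize = FALSE,
                       intercept = FALSE)
    lams <- make_lambda_path(lmax, 20, 0.05)
    fit <- pl_fit(d$x, d$y, group = g, method = m, alpha = 0.5,
                  family = "gaussian", lambda = lams,
                  standardize = FALSE, intercept = FALSE)
    for (i in c(5, 10, 20)) {
      spec <- penalty_spec(m, lams[i], 0.5)
      v <- check_optimality(d, g, fit$beta[, i], spec)
      expect_lt(v, 1e-4)
      pert <- fit$beta[, i]
      pert[1] <- pert[1] + 0.1
      expect_gt(check_optimality(d, g, pert, spec), v)
    }
  }
})

test_that("each group block is entirely zero or stationarity-active", {
  inst <- random_instance(71)
  d <- inst$data; g <- inst$groups
  fit <- pl_fit(d$x, d$y, group = g, method = "grouplasso",
                family = "gaussian", nlambda = 25)
  for (i in seq_along(fit$lambda)) {
    b <- fit$beta[, i]
    for (gr in g$groups) {
      blk <- b[g$group_of == gr]
      expect_true(all(blk == 0) || any(blk != 0))
      if (all(blk == 0)) expect_identical(unname(blk), rep(0, length(blk)))
    }
  }
  # group-level sparsity actually occurs somewhere along the path
  gcounts <- vapply(seq_along(fit$lambda), function(i) {
    sum(vapply(g$groups, function(gr)
      any(fit$beta[g$group_of == gr, i] != 0), logical(1)))
  }, numeric(1))
  expect_true(any(gcounts > 0 & gcounts < length(g$groups)))
})

test_that("block solutions match the independent FISTA oracle (spot check)", {
  for (family in c("gaussian", "binomial")) {
    inst <- random_instance(81, family = family)
    for (m in c("lasso", "grouplasso", "sgl")) {
      res <- solver_vs_oracle(inst, m, lambda_frac = 0.3)
      expect_lte(res["pkg"], res["oracle"] + 1e-6 * (1 + abs(res["oracle"])))
      expect_lt(res["kkt"], 1e-4)
    }
  }
})

test_that("constant columns are zeroed with a warning", {
  inst <- random_instance(91)
  x <- inst$data$x
  x[, 3] <- 5
  expect_warning(
    fit <- pl_fit(x, inst$data$y, group = inst$groups,
                  method = "grouplasso", family = "gaussian", nlambda = 10),
    "constant")
  expect_identical(unname(fit$beta[3, ]), rep(0, 10))
})

test_that("fit validates arguments", {
  inst <- random_instance(99)
  expect_error(pl_fit(inst$data$x, inst$data$y, method = "grouplasso"),
               "group")
  expect_error(pl_fit(inst$data$x, inst$data$y, group = inst$groups,
                      method = "sgl", alpha = 2), "alpha")
  expect_error(pl_fit(inst$data$x, inst$data$y, group = c("a", "b"),
                      method = "grouplasso"), "does not match")
})
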