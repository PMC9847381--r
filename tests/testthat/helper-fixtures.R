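# Small random instances for solver tests. Columns and (gaussian) response
# are pre-centered so fits with intercept = FALSE, standardize = FALSE work
# on exactly the objective the oracle sees.
random_instance <- function(seed, n = 50, p = 20, G = 5,
                            family = "gaussian", center = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("V", seq_len(p))
  group <- rep(paste0("g", seq_len(G)), each = p / G)
  beta <- rep(0, p)
  active <- sample(G, 2)
  for (g in active) {
    idx <- which(group == paste0("g", g))
    beta[idx] <- rnorm(length(idx))
  }
  eta <- drop(x %*% beta)
  if (family == "gaussian") {
    y <- eta + rnorm(n)
    if (center) {
      x <- scale(x, scale = FALSE)
      y <- y - mean(y)
    }
  } else {
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    if (center) x <- scale(x, scale = FALSE)
  }
  attr(x, "scaled:center") <- NULL
  list(data = polarlasso::pl_data(x, y, family = family),
       groups = polarlasso::group_structure(group),
       beta_true = beta)
}

# coefficient inputs mirroring the published group-lasso ALL summary used
# throughout the chart tests: CD3D -0.225 (1 var), HLA-DPB1 0.038 + a
# second member, TRDC 0.037
published_group_coefs <- function() {
  list(beta = c(CD3D = -0.225, `HLA-DPB1.1` = 0.038, `HLA-DPB1.2` = 0.036,
                TRDC = 0.037),
       group = c("CD3D", "HLA-DPB1", "HLA-DPB1", "TRDC"))
}

published_lasso_coefs <- function() {
  c(CD3D = 0.121, TNNI3 = 0.107, ACAP1 = 0.097)
}
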