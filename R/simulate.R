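# Seeded generator of grouped genomic-style data with known sparse truth.
# Emulates the structure penalized group methods are built for: blocks of
# correlated predictors (genes in a pathway, SNPs in a region), a few truly
# active blocks, optionally only a fraction of members active within them.

#' Simulation configuration
#'
#' Defaults describe the package's reference scenario: 200 samples, 10
#' groups of 5 exchangeably correlated predictors (within-group correlation
#' 0.3), 3 fully active groups with effect magnitudes uniform in
#' \[0.5, 1.5\] and random signs, and gaussian noise set from a
#' signal-to-noise ratio of 5 (`SNR = var(X beta) / sigma^2`).
#'
#' @param n Number of samples.
#' @param n_groups Number of predictor groups G.
#' @param group_size Common group size (or give `sizes`).
#' @param sizes Optional explicit per-group sizes (overrides `group_size`).
#' @param n_active Number of truly active groups, `1 <= n_active <= G`
#'   (0 allowed for a pure-noise design).
#' @param within_frac Fraction of members active within an active group,
#'   in (0, 1]; each active group keeps `ceiling(frac * size)` members.
#' @param effect_range Magnitude range of nonzero coefficients.
#' @param rho Within-group exchangeable correlation, in \[0, 1).
#' @param snr Target signal-to-noise ratio used to derive `sigma` when
#'   `sigma` is `NULL` (gaussian only).
#' @param sigma Gaussian noise standard deviation (> 0); overrides `snr`.
#' @param family `"gaussian"` or `"binomial"` (Bernoulli-logistic response).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   whole configuration.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n = 200, n_groups = 10, group_size = 5, sizes = NULL,
                       n_active = 3, within_frac = 1,
                       effect_range = c(0.5, 1.5), rho = 0.3,
                       snr = 5, sigma = NULL,
                       family = c("gaussian", "binomial"), seed = 1) {
  family <- match.arg(family)
  if (is.null(sizes)) sizes <- rep(as.integer(group_size), n_groups)
  sizes <- as.integer(sizes)
  if (length(sizes) != n_groups || any(sizes < 1))
    stop("'sizes' must give a positive size for each of the ", n_groups,
         " groups")
  if (n_active < 0 || n_active > n_groups)
    stop("'n_active' must be between 0 and ", n_groups)
  if (within_frac <= 0 || within_frac > 1)
    stop("'within_frac' must be in (0, 1]")
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  if (!is.null(sigma) && sigma <= 0) stop("'sigma' must be positive")
  if (is.null(sigma) && (is.null(snr) || snr <= 0))
    stop("give a positive 'snr' or a positive 'sigma'")
  if (length(effect_range) != 2 || any(effect_range < 0) ||
      effect_range[1] > effect_range[2])
    stop("'effect_range' must be an increasing nonnegative pair")
  structure(list(n = as.integer(n), n_groups = as.integer(n_groups),
                 sizes = sizes, n_active = as.integer(n_active),
                 within_frac = within_frac, effect_range = effect_range,
                 rho = rho, snr = snr, sigma = sigma, family = family,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: n=%d, %d groups (p=%d), %d active (frac %.2f), rho=%.2f, %s, seed %d\n",
    x$n, x$n_groups, sum(x$sizes), x$n_active, x$within_frac, x$rho,
    x$family, x$seed))
  invisible(x)
}

#' Noise level implied by a target signal-to-noise ratio
#'
#' With `SNR = var(X beta) / sigma^2`, returns
#' `sigma = sd(X beta) / sqrt(SNR)` for a realized linear predictor.
#'
#' @param linpred Realized linear predictor `X %*% beta`.
#' @param snr Target signal-to-noise ratio.
#' @return The implied `sigma`.
#' @export
snr_to_sigma <- function(linpred, snr) {
  s <- sd(linpred)
  if (s == 0) stop("linear predictor has zero variance; SNR is undefined")
  s / sqrt(snr)
}

#' Generate a grouped dataset with known sparse truth
#'
#' Draws the design block by block: within a group every column is
#' `sqrt(rho) * z_g + sqrt(1 - rho) * e_j` with a shared group factor
#' `z_g`, giving exchangeable within-group correlation `rho` and
#' independence across groups. True coefficients are nonzero only in
#' `n_active` randomly chosen groups and, within them, on a `within_frac`
#' fraction of members; magnitudes are uniform over `effect_range` with
#' random signs. The gaussian response is `X beta + N(0, sigma^2)` (sigma
#' from `snr` when not given); the binomial response is
#' `Bernoulli(plogis(X beta))`.
#'
#' @param config A [sim_config()].
#' @return List with `data` (a [pl_data()]), `groups`
#'   (a [group_structure()]), `beta_true` (named, length p),
#'   `active_groups` (labels), `sigma` (gaussian noise sd used), and
#'   `config`.
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n = 100, n_groups = 8, group_size = 5,
#'                                    n_active = 2, seed = 7))
#' dim(sim$data$x)
#' sim$active_groups
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    p <- sum(config$sizes)
    G <- config$n_groups
    glabels <- sprintf("G%02d", seq_len(G))
    group_of <- rep(glabels, times = config$sizes)
    x <- matrix(0, config$n, p)
    col <- 1
    for (g in seq_len(G)) {
      k <- config$sizes[g]
      z <- rnorm(config$n)
      e <- matrix(rnorm(config$n * k), config$n, k)
      x[, col:(col + k - 1)] <-
        sqrt(config$rho) * z + sqrt(1 - config$rho) * e
      col <- col + k
    }
    colnames(x) <- paste0("V", seq_len(p))

    beta <- rep(0, p)
    active <- sort(sample(G, config$n_active))
    for (g in active) {
      idx <- which(group_of == glabels[g])
      n_on <- ceiling(config$within_frac * length(idx))
      if (n_on < 1)
        stop("within_frac leaves no active members in group ", glabels[g])
      on <- sort(sample(idx, n_on))
      beta[on] <- runif(n_on, config$effect_range[1],
                        config$effect_range[2]) *
        sample(c(-1, 1), n_on, replace = TRUE)
    }
    names(beta) <- colnames(x)

    linpred <- drop(x %*% beta)
    if (config$family == "gaussian") {
      sigma <- if (!is.null(config$sigma)) config$sigma
               else if (config$n_active == 0 || all(beta == 0)) 1
               else snr_to_sigma(linpred, config$snr)
      y <- linpred + rnorm(config$n, sd = sigma)
    } else {
      sigma <- NA_real_
      y <- rbinom(config$n, 1, plogis(linpred))
      if (length(unique(y)) < 2) {
        # pathological draw; flip the most borderline sample
        i <- which.min(abs(plogis(linpred) - 0.5))
        y[i] <- 1 - y[i]
      }
    }
    list(data = pl_data(x, y, family = config$family),
         groups = group_structure(group_of),
         beta_true = beta, active_groups = glabels[active],
         sigma = sigma, config = config)
  })
}

#' Support-recovery experiment over many seeded replicates
#'
#' For each seed: generate a dataset from `config` (with that seed),
#' cross-validate the chosen method, take the coefficients at the selected
#' lambda, and compare the set of selected groups (any nonzero member)
#' against the truly active groups.
#'
#' @param config A [sim_config()]; its own seed is ignored in favor of
#'   `seeds`.
#' @param method `"lasso"`, `"grouplasso"`, or `"sgl"`.
#' @param k CV folds.
#' @param seeds Integer vector of replicate seeds (used for both data
#'   generation and fold assignment).
#' @param lambda_type `"min"` or `"1se"`.
#' @param alpha Sparse-group mixing weight.
#' @param ... Passed to [cv_pl_fit()].
#' @return List with `per_seed` (data frame: seed, n_selected,
#'   all_active_selected, n_false) and aggregate `recovery_rate` (fraction
#'   of seeds selecting every active group) and `mean_false_groups`.
#' @export
support_recovery_experiment <- function(config,
                                        method = c("grouplasso", "lasso",
                                                   "sgl"),
                                        k = 10, seeds = 1:20,
                                        lambda_type = c("min", "1se"),
                                        alpha = 0.95, ...) {
  method <- match.arg(method)
  lambda_type <- match.arg(lambda_type)
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    sim <- generate_dataset(cfg)
    cv <- cv_pl_fit(sim$data, group = sim$groups, method = method,
                    alpha = alpha, k = k, seed = s, ...)
    sel <- selected_groups(cv$fit, index = select_lambda(cv, lambda_type))
    data.frame(seed = s, n_selected = length(sel),
               all_active_selected =
                 all(sim$active_groups %in% sel),
               n_false = sum(!sel %in% sim$active_groups))
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       recovery_rate = mean(per_seed$all_active_selected),
       mean_false_groups = mean(per_seed$n_false))
}
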