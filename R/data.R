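#' Assemble and validate a modelling dataset
#'
#' Bundles a numeric design matrix and a response vector into a validated
#' `pl_data` object. The response family is inferred from `y` when not given:
#' a vector containing only 0 and 1 is treated as binomial, anything else as
#' gaussian.
#'
#' @param x Numeric matrix (or data frame coercible to one), n samples by
#'   p predictors. Column names become predictor names; unnamed columns get
#'   `V1..Vp`.
#' @param y Numeric response of length n. For the binomial family every value
#'   must be 0 or 1 and both classes must be present.
#' @param family `"gaussian"`, `"binomial"`, or `NULL` to infer from `y`.
#' @param predictor_names Optional character vector of p unique names,
#'   overriding column names.
#'
#' @return An object of class `pl_data`: a list with elements `x`, `y`,
#'   `family`, `predictor_names`, `n`, `p`, and `standardized` (a flag, set by
#'   fitting code when columns have been centered/scaled).
#' @export
#' @examples
#' d <- pl_data(matrix(rnorm(20), 5, 4), rnorm(5))
#' d$family
pl_data <- function(x, y, family = NULL, predictor_names = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix")
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("need at least 2 samples, got ", n)
  if (p < 1) stop("need at least 1 predictor")
  if (length(y) != n)
    stop("length of 'y' (", length(y), ") does not match nrow(x) (", n, ")")
  if (anyNA(x) || any(!is.finite(x)))
    stop("'x' contains missing or non-finite values")
  if (anyNA(y) || any(!is.finite(y)))
    stop("'y' contains missing or non-finite values")
  if (is.null(predictor_names)) predictor_names <- colnames(x)
  if (is.null(predictor_names)) predictor_names <- paste0("V", seq_len(p))
  predictor_names <- as.character(predictor_names)
  if (length(predictor_names) != p)
    stop("'predictor_names' must have length ", p)
  if (anyDuplicated(predictor_names))
    stop("predictor names must be unique; duplicated: ",
         paste(unique(predictor_names[duplicated(predictor_names)]),
               collapse = ", "))
  binaryish <- all(y %in% c(0, 1))
  if (is.null(family)) family <- if (binaryish) "binomial" else "gaussian"
  family <- match.arg(family, c("gaussian", "binomial"))
  if (family == "binomial") {
    if (!binaryish)
      stop("family 'binomial' requires y values in {0, 1}")
    if (length(unique(y)) < 2)
      stop("family 'binomial' requires both classes present in y")
  }
  colnames(x) <- predictor_names
  structure(list(x = x, y = y, family = family,
                 predictor_names = predictor_names,
                 n = n, p = p, standardized = FALSE),
            class = "pl_data")
}

#' @export
print.pl_data <- function(x, ...) {
  cat(sprintf("pl_data: %d samples x %d predictors, family = %s\n",
              x$n, x$p, x$family))
  invisible(x)
}

#' Define a predictor group structure
#'
#' Maps each predictor to exactly one group and attaches per-group penalty
#' weights. Groups are ordered by first appearance in `group`. The default
#' weight of group g is `sqrt(size_g)`, the usual group-lasso choice that
#' keeps large groups from being favored merely for having many members.
#'
#' @param group Vector of p group labels (character, factor, or integer), one
#'   per predictor, in the column order of the design matrix.
#' @param weights Optional positive per-group weights, either unnamed in group
#'   order or named by group label. Default `sqrt(sizes)`.
#'
#' @return Object of class `pl_groups`: list with `group_of` (character,
#'   length p), `groups` (G labels in first-appearance order), `sizes`, and
#'   `weights` (both named by group).
#' @export
#' @examples
#' g <- group_structure(c("a", "a", "b", "c", "c", "c"))
#' g$sizes
#' g$weights  # sqrt of sizes
group_structure <- function(group, weights = NULL) {
  if (inherits(group, "pl_groups")) return(group)
  group <- as.character(group)
  if (length(group) < 1) stop("'group' must have at least one element")
  if (anyNA(group)) stop("'group' contains missing labels")
  groups <- unique(group)
  sizes <- vapply(groups, function(g) sum(group == g), integer(1))
  names(sizes) <- groups
  if (is.null(weights)) {
    weights <- sqrt(sizes)
  } else {
    weights <- unlist(weights)
    if (!is.null(names(weights))) {
      if (!all(groups %in% names(weights)))
        stop("named 'weights' must cover every group")
      weights <- weights[groups]
    } else if (length(weights) != length(groups)) {
      stop("'weights' must have one entry per group (", length(groups), ")")
    }
    weights <- as.numeric(weights)
    names(weights) <- groups
  }
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("group weights must be positive and finite")
  structure(list(group_of = group, groups = groups,
                 sizes = sizes, weights = weights),
            class = "pl_groups")
}

#' @export
print.pl_groups <- function(x, ...) {
  cat(sprintf("pl_groups: %d predictors in %d groups (sizes %s)\n",
              length(x$group_of), length(x$groups),
              paste(range(x$sizes), collapse = "-")))
  invisible(x)
}

# check a groups object against a dataset / coefficient length
check_group_dims <- function(groups, p) {
  if (length(groups$group_of) != p)
    stop("group vector length (", length(groups$group_of),
         ") does not match number of predictors (", p, ")")
  invisible(groups)
}
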