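# Multi-level polar chart geometry. Everything here is pure computation on
# coefficients: ranking, sector partition, radii, inner points, colors. No
# drawing happens in this file, so the geometry is testable on its own.

#' Rank groups by their coefficient impact
#'
#' Keeps only groups with at least one nonzero coefficient, computes each
#' group's ranking feature — the maximum (`sort_type = "max"`) or mean
#' (`"mean"`) of the absolute values of its nonzero coefficients — and sorts
#' descending by feature, ties broken by group label.
#'
#' @param beta Named coefficient vector, or unnamed with `predictor_names`.
#' @param groups A [group_structure()] (or group label vector).
#' @param sort_type `"max"` (default) or `"mean"`.
#' @param predictor_names Names for `beta` if it is unnamed.
#' @return Object of class `pl_group_summary`: list with `table` (data frame
#'   `group`, `size`, `feature`, sorted) and `members` (data frame `group`,
#'   `variable`, `coefficient` of nonzero members). `size` counts a group's
#'   displayed (nonzero) variables.
#' @export
#' @examples
#' b <- c(CD3D = -0.225, HLADPB1a = 0.038, HLADPB1b = 0.036, TRDC = 0.037)
#' g <- c("CD3D", "HLA-DPB1", "HLA-DPB1", "TRDC")
#' summarize_groups(b, g)$table
summarize_groups <- function(beta, groups, sort_type = c("max", "mean"),
                             predictor_names = names(beta)) {
  sort_type <- match.arg(sort_type)
  beta <- as.numeric(stats::setNames(beta, predictor_names))
  if (is.null(predictor_names))
    stop("coefficients must be named (or supply 'predictor_names')")
  groups <- group_structure(groups)
  check_group_dims(groups, length(beta))
  nz <- beta != 0
  if (!any(nz))
    stop("all coefficients are zero; nothing to chart. ",
         "Lower lambda (or use lambda.min) to retain variables.")
  keep <- groups$groups[vapply(groups$groups, function(g)
    any(nz[groups$group_of == g]), logical(1))]
  feat_fun <- if (sort_type == "max") max else mean
  tab <- data.frame(
    group = keep,
    size = vapply(keep, function(g)
      sum(nz & groups$group_of == g), integer(1)),
    feature = vapply(keep, function(g)
      feat_fun(abs(beta[nz & groups$group_of == g])), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$feature, tab$group), , drop = FALSE]
  rownames(tab) <- NULL
  members <- data.frame(
    group = groups$group_of[nz],
    variable = predictor_names[nz],
    coefficient = beta[nz],
    stringsAsFactors = FALSE, row.names = NULL)
  members <- members[members$group %in% keep, , drop = FALSE]
  structure(list(table = tab, members = members, sort_type = sort_type),
            class = "pl_group_summary")
}

#' Truncate a group summary to the strongest groups
#'
#' @param summaries A [summarize_groups()] result (already sorted).
#' @param max_shown Keep at most this many groups; `NULL` keeps all.
#' @return The truncated `pl_group_summary`; a message reports how many
#'   groups were hidden.
#' @export
apply_max_shown <- function(summaries, max_shown = NULL) {
  if (is.null(max_shown)) return(summaries)
  if (!is.numeric(max_shown) || max_shown < 1)
    stop("'max_shown' must be a positive integer")
  n_all <- nrow(summaries$table)
  keep <- min(n_all, as.integer(max_shown))
  message("showing ", keep, " of ", n_all, " groups (",
          n_all - keep, " hidden)")
  summaries$table <- summaries$table[seq_len(keep), , drop = FALSE]
  summaries$members <-
    summaries$members[summaries$members$group %in% summaries$table$group, ,
                      drop = FALSE]
  summaries
}

#' Resolve the polar geometry of a chart
#'
#' The circle is divided into as many equal sectors as there are displayed
#' groups, laid out counterclockwise from 0 degrees in rank order (rank 1
#' starts at 0). Sector radius is the group's ranking feature divided by the
#' largest feature, so the rank-1 sector has radius 1. Each nonzero member
#' variable becomes an inner point at relative radius `|beta_j|` divided by
#' the largest `|beta|` in its group, placed on the sector midline plus a
#' deterministic uniform angular jitter confined to the central 80% of the
#' sector. Point symbols record the coefficient sign; tooltips read
#' "group / variable / coefficient" with the coefficient to 4 decimals.
#'
#' @param summaries A [summarize_groups()] result (optionally truncated by
#'   [apply_max_shown()]).
#' @param jitter_seed Integer seed for the angular jitter.
#' @param lambda_used Optional lambda value recorded in the layout.
#' @return Object of class `pl_layout`: list with data frames `sectors`
#'   (`group`, `rank`, `start_deg`, `end_deg`, `radius`, `size`, `feature`,
#'   and after [assign_styles()] `color_value`, `color`) and `points`
#'   (`group`, `variable`, `coefficient`, `angle_deg`, `rel_radius`,
#'   `symbol`, `tooltip`), plus `sort_type`, `lambda_used`, `jitter_seed`,
#'   `lasso_mode`.
#' @export
compute_layout <- function(summaries, jitter_seed = 1, lambda_used = NULL) {
  tab <- summaries$table
  G <- nrow(tab)
  if (G < 1) stop("no groups to lay out")
  width <- 360 / G
  sectors <- data.frame(
    group = tab$group,
    rank = seq_len(G),
    start_deg = (seq_len(G) - 1) * width,
    end_deg = seq_len(G) * width,
    radius = tab$feature / max(tab$feature),
    size = tab$size,
    feature = tab$feature,
    stringsAsFactors = FALSE, row.names = NULL)

  m <- summaries$members
  m <- m[order(match(m$group, tab$group), m$variable), , drop = FALSE]
  sec_of <- match(m$group, tab$group)
  gmax <- vapply(tab$group, function(g)
    max(abs(m$coefficient[m$group == g])), numeric(1))
  mid <- (sectors$start_deg + sectors$end_deg)[sec_of] / 2
  jit <- with_seed(jitter_seed,
                   runif(nrow(m), -0.4, 0.4)) * width
  points <- data.frame(
    group = m$group,
    variable = m$variable,
    coefficient = m$coefficient,
    angle_deg = mid + jit,
    rel_radius = abs(m$coefficient) / gmax[sec_of],
    symbol = ifelse(m$coefficient < 0, "negative", "positive"),
    tooltip = sprintf("%s / %s / %.4f", m$group, m$variable, m$coefficient),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(sectors = sectors, points = points,
                 sort_type = summaries$sort_type,
                 lambda_used = lambda_used,
                 jitter_seed = as.integer(jitter_seed),
                 lasso_mode = isTRUE(summaries$lasso_mode)),
            class = "pl_layout")
}

#' Attach size-encoding colors to a layout
#'
#' Maps displayed group sizes to a color value in \[0, 1\] (0 = brightest =
#' smallest displayed group, 1 = darkest = largest), linearly in size, and
#' renders it to a hex color on a single-hue lightness ramp. Normalization
#' uses only the displayed groups, so the spectrum readjusts after
#' truncation. Equal sizes map to a common mid value.
#'
#' @param layout A [compute_layout()] result.
#' @param hue HCL hue of the ramp (default 260, blue).
#' @return The layout with `color_value` and `color` sector columns.
#' @export
assign_styles <- function(layout, hue = 260) {
  s <- layout$sectors
  rng <- range(s$size)
  cv <- if (rng[1] == rng[2]) rep(0.5, nrow(s))
        else (s$size - rng[1]) / (rng[2] - rng[1])
  layout$sectors$color_value <- cv
  layout$sectors$color <- size_color(cv, hue)
  layout
}

# darkness value in [0,1] -> hex color; brighter = smaller group
size_color <- function(cv, hue = 260) {
  grDevices::hcl(h = hue, c = 35 + 30 * cv, l = 88 - 55 * cv)
}

#' Lasso-mode chart layout
#'
#' Without a group structure every selected (nonzero) variable becomes its
#' own size-1 group, and the usual pipeline applies: each sector holds
#' exactly one point at relative radius 1.
#'
#' @param beta Named coefficient vector (or use `predictor_names`).
#' @param predictor_names Names for `beta` if unnamed.
#' @param max_shown Optional cap on the number of sectors.
#' @param jitter_seed Seed for angular jitter.
#' @param lambda_used Optional lambda value recorded in the layout.
#' @return A styled `pl_layout` with `lasso_mode = TRUE`.
#' @export
lasso_layout <- function(beta, predictor_names = names(beta),
                         max_shown = NULL, jitter_seed = 1,
                         lambda_used = NULL) {
  beta <- stats::setNames(as.numeric(beta), predictor_names)
  if (is.null(predictor_names)) stop("coefficients must be named")
  s <- summarize_groups(beta, predictor_names, sort_type = "max",
                        predictor_names = predictor_names)
  s$lasso_mode <- TRUE
  s <- apply_max_shown(s, max_shown)
  assign_styles(compute_layout(s, jitter_seed = jitter_seed,
                               lambda_used = lambda_used))
}

#' One-call chart layout from a fit, CV result, or coefficient table
#'
#' Convenience wrapper running [summarize_groups()], [apply_max_shown()],
#' [compute_layout()], and [assign_styles()]. Dispatches on its input:
#' a numeric coefficient vector plus `group`, a [cv_pl_fit()] result (with
#' `lambda_type` `"min"` or `"1se"`), or a coefficient table data frame with
#' columns `variable`, `group`, `coefficient`. Lasso fits (or inputs whose
#' groups all have one member and carry the variable's own name) use
#' [lasso_layout()].
#'
#' @param x Coefficient vector, `pl_cv`, `pl_fit`, or data frame.
#' @param ... Passed on to methods.
#' @return A styled `pl_layout`.
#' @export
chart_layout <- function(x, ...) UseMethod("chart_layout")

#' @rdname chart_layout
#' @param group Group labels or [group_structure()]; `NULL` for lasso mode.
#' @param sort_type `"max"` or `"mean"`.
#' @param max_shown Optional sector cap.
#' @param jitter_seed Seed for angular jitter.
#' @param lambda_used Optional lambda value recorded in the layout.
#' @export
chart_layout.numeric <- function(x, group = NULL,
                                 sort_type = c("max", "mean"),
                                 max_shown = NULL, jitter_seed = 1,
                                 lambda_used = NULL, ...) {
  if (is.null(group))
    return(lasso_layout(x, max_shown = max_shown,
                        jitter_seed = jitter_seed,
                        lambda_used = lambda_used))
  s <- summarize_groups(x, group, sort_type = sort_type)
  s <- apply_max_shown(s, max_shown)
  assign_styles(compute_layout(s, jitter_seed = jitter_seed,
                               lambda_used = lambda_used))
}

#' @rdname chart_layout
#' @param lambda_type `"min"` (default) or `"1se"`: which cross-validated
#'   lambda's coefficients to chart.
#' @export
chart_layout.pl_cv <- function(x, lambda_type = c("min", "1se"),
                               sort_type = c("max", "mean"),
                               max_shown = NULL, jitter_seed = 1, ...) {
  lambda_type <- match.arg(lambda_type)
  i <- select_lambda(x, lambda_type)
  b <- x$fit$beta[, i]
  if (x$method == "lasso")
    return(lasso_layout(b, max_shown = max_shown,
                        jitter_seed = jitter_seed,
                        lambda_used = x$lambda[i]))
  chart_layout.numeric(b, group = x$fit$groups, sort_type = sort_type,
                       max_shown = max_shown, jitter_seed = jitter_seed,
                       lambda_used = x$lambda[i])
}

#' @rdname chart_layout
#' @param index Path position for a `pl_fit` input (default: last lambda).
#' @export
chart_layout.pl_fit <- function(x, index = NULL,
                                sort_type = c("max", "mean"),
                                max_shown = NULL, jitter_seed = 1, ...) {
  i <- resolve_index(x, index)
  b <- x$beta[, i]
  if (x$method == "lasso")
    return(lasso_layout(b, max_shown = max_shown,
                        jitter_seed = jitter_seed,
                        lambda_used = x$lambda[i]))
  chart_layout.numeric(b, group = x$groups, sort_type = sort_type,
                       max_shown = max_shown, jitter_seed = jitter_seed,
                       lambda_used = x$lambda[i])
}

#' @rdname chart_layout
#' @export
chart_layout.data.frame <- function(x, sort_type = c("max", "mean"),
                                    max_shown = NULL, jitter_seed = 1,
                                    lambda_used = NULL, ...) {
  need <- c("variable", "group", "coefficient")
  if (!all(need %in% names(x)))
    stop("coefficient table needs columns: ", paste(need, collapse = ", "))
  b <- stats::setNames(as.numeric(x$coefficient), as.character(x$variable))
  lasso_like <- all(as.character(x$group) == as.character(x$variable))
  if (lasso_like)
    return(lasso_layout(b, max_shown = max_shown,
                        jitter_seed = jitter_seed,
                        lambda_used = lambda_used))
  chart_layout.numeric(b, group = as.character(x$group),
                       sort_type = sort_type, max_shown = max_shown,
                       jitter_seed = jitter_seed, lambda_used = lambda_used)
}

#' @export
print.pl_layout <- function(x, ...) {
  cat(sprintf("pl_layout: %d sectors, %d points (sort_type = %s%s)\n",
              nrow(x$sectors), nrow(x$points), x$sort_type,
              if (isTRUE(x$lasso_mode)) ", lasso mode" else ""))
  invisible(x)
}
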