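# Tabular readers. Delimiter is auto-detected (comma vs tab) from the
# header line; decimal points only. Errors name the file and the offending
# rows/columns so inputs exported from other tools can be fixed quickly.

detect_sep <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) stop("empty file: ", path)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

read_table_auto <- function(path) {
  df <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0) stop("no data rows in ", path)
  df
}

#' Read a design matrix, response, and group vector from delimited files
#'
#' `x_path` holds the n x p design matrix with a header of predictor names;
#' `y_path` a single response column (or name a column of the design file
#' via `y_column`); `group_path` one group label per predictor, in the
#' column order of the design matrix — the same order used when the model is
#' fitted. Files may be comma- or tab-delimited.
#'
#' @param x_path Path to the design matrix file.
#' @param y_path Path to the response file (single column with header).
#' @param group_path Path to the group file (single column with header, p
#'   rows).
#' @param y_column Alternative to `y_path`: name of the response column
#'   inside the design file (removed from the predictors).
#' @param family `"gaussian"`, `"binomial"`, or `NULL` to infer (binary 0/1
#'   response implies binomial).
#' @return List with `data` (a [pl_data()]) and `groups`
#'   (a [group_structure()]).
#' @export
read_design <- function(x_path, y_path = NULL, group_path,
                        y_column = NULL, family = NULL) {
  xdf <- read_table_auto(x_path)
  if (!is.null(y_column)) {
    if (!y_column %in% names(xdf))
      stop("column '", y_column, "' not found in ", x_path)
    y <- xdf[[y_column]]
    xdf[[y_column]] <- NULL
  } else {
    if (is.null(y_path)) stop("supply 'y_path' or 'y_column'")
    ydf <- read_table_auto(y_path)
    y <- ydf[[1]]
    if (length(y) != nrow(xdf))
      stop("response length (", length(y), ") in ", y_path,
           " does not match rows of ", x_path, " (", nrow(xdf), ")")
  }
  bad <- !vapply(xdf, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric predictor column(s) in ", x_path, ": ",
         paste(names(xdf)[bad], collapse = ", "))
  x <- as.matrix(xdf)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)
    idx <- idx[seq_len(min(nrow(idx), 10)), , drop = FALSE]
    stop("missing values in ", x_path, " at (row, column): ",
         paste(sprintf("(%d, %s)", idx[, 1], colnames(x)[idx[, 2]]),
               collapse = ", "))
  }
  if (anyNA(y))
    stop("missing values in response at row(s): ",
         paste(head(which(is.na(y)), 10), collapse = ", "))
  gdf <- read_table_auto(group_path)
  group <- as.character(gdf[[1]])
  if (length(group) != ncol(x))
    stop("group vector length (", length(group), ") in ", group_path,
         " does not match number of predictors (", ncol(x), ") in ", x_path)
  if (!is.null(family) && family == "binomial" && !all(y %in% c(0, 1)))
    stop("family 'binomial' requested but response in ",
         if (is.null(y_path)) x_path else y_path, " is not 0/1")
  list(data = pl_data(x, y, family = family),
       groups = group_structure(group))
}

#' Read a coefficient table
#'
#' The chart-only entry point: a delimited file with header columns
#' `variable`, `group`, `coefficient` (any column order), as written by
#' [write_coefficient_table()] or exported from any fitting tool. Zero
#' coefficients are retained here; [summarize_groups()] filters them.
#'
#' @param path File path (comma- or tab-delimited).
#' @return Validated data frame with character `variable`/`group` and
#'   numeric `coefficient`.
#' @export
read_coefficient_table <- function(path) {
  df <- read_table_auto(path)
  need <- c("variable", "group", "coefficient")
  if (!all(need %in% names(df)))
    stop(path, " must have columns: ", paste(need, collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")")
  coefs <- suppressWarnings(as.numeric(df$coefficient))
  if (anyNA(coefs))
    stop("non-numeric coefficient in ", path, " at row(s): ",
         paste(head(which(is.na(coefs)), 10), collapse = ", "))
  out <- data.frame(variable = as.character(df$variable),
                    group = as.character(df$group),
                    coefficient = coefs, stringsAsFactors = FALSE)
  if (anyDuplicated(out$variable))
    stop("duplicate variable name(s) in ", path, ": ",
         paste(unique(out$variable[duplicated(out$variable)]),
               collapse = ", "))
  out
}

#' Write a coefficient table
#'
#' @param table Data frame with columns `variable`, `group`, `coefficient`
#'   (or a named coefficient vector plus `group` labels).
#' @param path Output CSV path.
#' @param group Group labels when `table` is a coefficient vector.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(table, path, group = NULL) {
  if (is.numeric(table)) {
    if (is.null(names(table))) stop("coefficient vector must be named")
    if (is.null(group)) group <- names(table)
    gs <- group_structure(group)
    table <- data.frame(variable = names(table), group = gs$group_of,
                        coefficient = as.numeric(table),
                        stringsAsFactors = FALSE)
  }
  write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# write atomically so failures never leave partial output behind
write_atomic <- function(text, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writeLines(text, tmp, useBytes = TRUE)
  if (!file.rename(tmp, path)) stop("cannot write ", path)
  ok <- TRUE
  invisible(path)
}

#' Serialize a chart layout to JSON
#'
#' Writes the fully resolved geometry (sectors, points, options) at full
#' double precision (angles carry at least 15 significant digits), following
#' the schema in `system.file("extdata", "layout-schema.json", package =
#' "polarlasso")`. [read_layout()] restores an identical layout.
#'
#' @param layout A `pl_layout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  obj <- list(
    sort_type = layout$sort_type,
    lambda_used = if (is.null(layout$lambda_used)) NULL
                  else layout$lambda_used,
    jitter_seed = layout$jitter_seed,
    lasso_mode = isTRUE(layout$lasso_mode),
    sectors = layout$sectors,
    points = layout$points)
  json <- jsonlite::toJSON(obj, dataframe = "rows", digits = NA,
                           auto_unbox = TRUE, null = "null", pretty = TRUE)
  write_atomic(json, path)
}

#' Read a chart layout from JSON
#'
#' @param path A file written by [write_layout()].
#' @return A `pl_layout`.
#' @export
read_layout <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("sort_type", "jitter_seed", "sectors", "points")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop(path, " is not a layout file; missing field(s): ",
         paste(miss, collapse = ", "))
  sec_cols <- c("group", "rank", "start_deg", "end_deg", "radius", "size",
                "feature")
  if (!all(sec_cols %in% names(obj$sectors)))
    stop(path, ": sectors lack required fields")
  structure(list(sectors = as.data.frame(obj$sectors),
                 points = as.data.frame(obj$points),
                 sort_type = obj$sort_type,
                 lambda_used = obj$lambda_used,
                 jitter_seed = as.integer(obj$jitter_seed),
                 lasso_mode = isTRUE(obj$lasso_mode)),
            class = "pl_layout")
}
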