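# Covariate standardization and collinearity screening.

#' Z-transform site covariates
#'
#' Centers and scales numeric covariates to mean 0, SD 1 (sample SD, n - 1
#' denominator) and stores the transform parameters so prediction-grid
#' covariates can be standardized with the *training* moments and estimates
#' can be back-transformed.
#'
#' @param table site covariate data frame.
#' @param columns covariate columns to standardize; defaults to all numeric
#'   columns except identifiers (`station_id`, `year`).
#' @return the table with the selected columns replaced by z-scores, class
#'   `std_covariates`, with `attr(, "transform_params")` a named list of
#'   `c(mean, sd)` per column.
#' @export
z_transform <- function(table, columns = NULL) {
  if (is.null(columns)) {
    num <- vapply(table, is.numeric, logical(1))
    columns <- setdiff(names(table)[num], c("year", "station_id"))
  }
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop_("columns not present: %s", paste(missing_cols, collapse = ", "))
  params <- list()
  for (v in columns) {
    x <- table[[v]]
    if (anyNA(x)) stop_("missing values in covariate '%s'", v)
    if (length(unique(x)) < 2L || sd(x) == 0)
      stop_("covariate '%s' has zero variance and cannot be standardized", v)
    m <- mean(x); s <- sd(x)
    table[[v]] <- (x - m) / s
    params[[v]] <- c(mean = m, sd = s)
  }
  structure(table, transform_params = params,
            class = c("std_covariates", class(table)))
}

#' Transform parameters of a standardized covariate table
#' @param x a `std_covariates` object.
#' @return named list of `c(mean, sd)` per standardized column.
#' @export
transform_params <- function(x) attr(x, "transform_params")

#' Apply stored z-transform parameters to new data
#'
#' Standardizes new covariates (e.g. a prediction grid) with the training
#' means/SDs retained by [z_transform()].
#'
#' @param table new covariate data frame.
#' @param params transform parameters from [transform_params()].
#' @return table with the parameterized columns z-scored.
#' @export
apply_z_transform <- function(table, params) {
  for (v in names(params)) {
    if (!v %in% names(table)) stop_("column '%s' missing from new data", v)
    table[[v]] <- (table[[v]] - params[[v]]["mean"]) / params[[v]]["sd"]
  }
  table
}

#' Invert a z-transform
#'
#' @param table standardized data frame.
#' @param params transform parameters from [transform_params()].
#' @return table on the original covariate scales.
#' @export
invert_z_transform <- function(table, params) {
  for (v in names(params)) {
    if (!v %in% names(table)) next
    table[[v]] <- table[[v]] * params[[v]]["sd"] + params[[v]]["mean"]
  }
  table
}

#' Spearman collinearity screen
#'
#' Computes rank (Spearman) correlations between all pairs of numeric
#' covariates, handling ties by midranks, and flags pairs whose absolute
#' correlation meets the threshold, the conventional pre-modeling
#' collinearity check.
#'
#' @param table covariate data frame (>= 3 rows).
#' @param threshold flagging threshold on |rho| (default 0.70).
#' @param columns columns to screen; defaults as in [z_transform()].
#' @return object of class `correlation_screen`: list with `rho` (symmetric
#'   matrix), `threshold`, and `flagged_pairs` (data frame var1/var2/rho).
#' @export
spearman_screen <- function(table, threshold = 0.70, columns = NULL) {
  assert_number(threshold, "threshold", lower = 0, upper = 1)
  if (is.null(columns)) {
    num <- vapply(table, is.numeric, logical(1))
    columns <- setdiff(names(table)[num], c("year", "station_id"))
  }
  if (nrow(table) < 3L)
    stop_("at least 3 rows are required for a correlation screen")
  x <- as.matrix(table[, columns, drop = FALSE])
  rho <- cor(x, method = "spearman")
  idx <- which(upper.tri(rho) & abs(rho) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(
    var1 = colnames(rho)[idx[, 1]],
    var2 = colnames(rho)[idx[, 2]],
    rho = rho[idx],
    stringsAsFactors = FALSE)
  structure(list(rho = rho, threshold = threshold, flagged_pairs = flagged),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> %d covariates, threshold |rho| >= %.2f\n",
              ncol(x$rho), x$threshold))
  if (nrow(x$flagged_pairs) == 0) {
    cat("no correlated pairs\n")
  } else {
    print(x$flagged_pairs)
  }
  invisible(x)
}
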