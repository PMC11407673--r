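# Gridded projection of the fitted occupancy model.

#' Build a regular prediction grid
#'
#' Tiles a rectangular extent (projected meters) with square cells of
#' `cell_size`, row-major from the top-left; partial edge cells are
#' retained with the true centroid of their clipped area.
#'
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)` in projected
#'   meters.
#' @param cell_size cell edge length in meters (default 500, the modeling
#'   scale).
#' @return data frame of class `prediction_grid` with `cell_id`, centroid
#'   `x`, `y`, and cell `width`/`height`; covariate columns are added by
#'   the user before prediction.
#' @export
make_grid <- function(extent, cell_size = 500) {
  assert_number(cell_size, "cell_size", lower = 1e-9)
  if (length(extent) != 4L || !is.numeric(extent))
    stop_("extent must be c(xmin, xmax, ymin, ymax)")
  xmin <- extent[1]; xmax <- extent[2]; ymin <- extent[3]; ymax <- extent[4]
  if (xmax <= xmin || ymax <= ymin)
    stop_("degenerate extent: xmax must exceed xmin and ymax exceed ymin")
  nx <- ceiling((xmax - xmin) / cell_size)
  ny <- ceiling((ymax - ymin) / cell_size)
  row <- rep(seq_len(ny), each = nx)
  col <- rep(seq_len(nx), times = ny)
  x_left <- xmin + (col - 1) * cell_size
  x_right <- pmin(x_left + cell_size, xmax)
  y_top <- ymax - (row - 1) * cell_size
  y_bottom <- pmax(y_top - cell_size, ymin)
  out <- data.frame(cell_id = seq_along(row),
                    x = (x_left + x_right) / 2,
                    y = (y_top + y_bottom) / 2,
                    width = x_right - x_left,
                    height = y_top - y_bottom)
  attr(out, "cell_size") <- cell_size
  attr(out, "dims") <- c(nrow = ny, ncol = nx)
  class(out) <- c("prediction_grid", "data.frame")
  out
}

#' Predict habitat-use probability on a grid
#'
#' Projects the occupancy side of a fitted model onto grid cells: cell
#' covariates are standardized with the *training* transform parameters,
#' the per-draw linear predictor is inverted through the logit link, and
#' cells are summarized by the posterior mean and 95% interval. The random
#' station intercept is set to zero in `"conditional"` mode (the
#' typical-station surface, default) or freshly drawn from
#' `Normal(0, sigma)` per draw and cell in `"marginal"` mode. Detection
#' covariates play no role: the surface is habitat use only.
#'
#' @param fit an `occu_fit`.
#' @param grid a [make_grid()] result (or any data frame) carrying the
#'   model's occupancy covariates on their original scales.
#' @param params transform parameters from [transform_params()] of the
#'   training covariates.
#' @param mode `"conditional"` or `"marginal"`.
#' @param seed RNG seed for marginal-mode draws.
#' @param extrapolation_sd threshold (in training SDs) beyond which a cell
#'   covariate triggers an extrapolation warning.
#' @return the grid with columns `psi_mean`, `psi_lo`, `psi_hi` appended.
#' @export
predict_psi <- function(fit, grid, params, mode = c("conditional", "marginal"),
                        seed = 1, extrapolation_sd = 4) {
  mode <- match.arg(mode)
  spec <- fit$spec
  dr <- extract_draws(fit)
  terms <- spec$psi_terms
  n <- nrow(grid); D <- length(dr$beta0)
  X <- matrix(0, n, 0)
  if (length(terms)) {
    cols <- lapply(terms, function(v) {
      if (!v %in% names(grid)) stop_("grid lacks covariate '%s'", v)
      if (v == "year" && !is.null(fit$design$year_params)) {
        yp <- fit$design$year_params
        (grid[[v]] - yp["mean"]) / yp["sd"]
      } else {
        if (!v %in% names(params))
          stop_("no transform parameters for '%s'", v)
        (grid[[v]] - params[[v]]["mean"]) / params[[v]]["sd"]
      }
    })
    X <- do.call(cbind, cols)
    colnames(X) <- terms
    n_extra <- sum(apply(abs(X) > extrapolation_sd, 1, any))
    if (n_extra > 0)
      warning(sprintf(
        "%d grid cell(s) lie beyond %.0f training SDs of a covariate (extrapolation)",
        n_extra, extrapolation_sd), call. = FALSE)
  }
  eta <- matrix(dr$beta0, n, D, byrow = TRUE)
  if (ncol(X) > 0) eta <- eta + X %*% t(dr$Beta)
  if (mode == "marginal") {
    if (is.null(dr$sigma))
      stop_("marginal mode requires a random station intercept in the model")
    eta <- eta + with_seed_(seed,
      matrix(rnorm(n * D), n, D) * matrix(dr$sigma, n, D, byrow = TRUE))
  }
  psi <- plogis(eta)
  grid$psi_mean <- rowMeans(psi)
  qs <- apply(psi, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  grid$psi_lo <- qs[1, ]
  grid$psi_hi <- qs[2, ]
  grid
}

#' Write a predicted habitat-use surface
#'
#' Writes the cell summaries as delimited text (`cell_id, x, y, psi_mean,
#' psi_lo, psi_hi`). Georeferenced raster output is not supported by this
#' package; export the delimited table to a GIS instead.
#'
#' @param grid a predicted grid from [predict_psi()].
#' @param path output file path.
#' @param format only `"csv"`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(grid, path, format = "csv") {
  if (!identical(format, "csv"))
    stop_("unsupported surface format '%s'; only delimited text ('csv') is available",
          format)
  cols <- c("cell_id", "x", "y", "psi_mean", "psi_lo", "psi_hi")
  missing_cols <- setdiff(cols, names(grid))
  if (length(missing_cols))
    stop_("grid is missing columns: %s", paste(missing_cols, collapse = ", "))
  write.csv(as.data.frame(grid)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a habitat-use surface written by [write_surface()]
#' @param path file path.
#' @return data frame of cell summaries.
#' @export
read_surface <- function(path) read.csv(path)
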