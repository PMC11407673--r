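# Readers and writers for the pipeline's delimited-text dialects, plus
# thin spreadsheet readers for deposited supplementary datasets.

#' Write / read camera-trap record tables
#'
#' Records are stored as delimited text with `station_id` and an ISO-8601
#' `timestamp`.
#'
#' @param records record data frame.
#' @param path file path.
#' @return `read_records()` returns the record table with parsed POSIXct
#'   timestamps (UTC).
#' @export
write_records <- function(records, path) {
  records <- check_records(records)
  out <- data.frame(station_id = records$station_id,
                    timestamp = format(records$timestamp,
                                       "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) check_records(read.csv(path))

#' Write / read deployment tables
#'
#' @param deployments deployment data frame (`station_id`, `start_date`,
#'   `end_date`, optionally `survey`, `year`).
#' @param path file path.
#' @return `read_deployments()` returns the deployment table with Date
#'   columns.
#' @export
write_deployments <- function(deployments, path) {
  write.csv(deployments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deployments
#' @export
read_deployments <- function(path) {
  d <- read.csv(path)
  d$start_date <- as.Date(d$start_date)
  d$end_date <- as.Date(d$end_date)
  d
}

#' Write / read site covariate tables
#'
#' The reader flags whether the stored covariates appear already z-scored
#' (every numeric column with mean ~0 and SD ~1) via
#' `attr(, "standardized")`; raw values are required to reproduce the
#' study-scale covariate moments.
#'
#' @param covariates site covariate data frame.
#' @param path file path.
#' @return `read_covariates()` returns the covariate table.
#' @export
write_covariates <- function(covariates, path) {
  write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  x <- read.csv(path)
  flag_standardized_(x)
}

flag_standardized_ <- function(x) {
  num <- vapply(x, is.numeric, logical(1))
  num[names(x) %in% c("year", "station_id")] <- FALSE
  std <- FALSE
  if (any(num)) {
    m <- vapply(x[num], mean, numeric(1))
    s <- vapply(x[num], sd, numeric(1))
    std <- all(abs(m) < 0.05) && all(abs(s - 1) < 0.05)
  }
  attr(x, "standardized") <- std
  x
}

#' Write / read detection history matrices
#'
#' The detection matrix dialect stores one row per stacked site with
#' leading identifier columns (`station_id`, `year`, optionally `survey`)
#' and occasion columns `o1..oK`; missing occasions are `NA`. The effort
#' matrix lives in a parallel file with the same layout.
#'
#' @param history a [detection_history].
#' @param prefix file-path prefix; `<prefix>_y.csv` and
#'   `<prefix>_effort.csv` are written.
#' @return `read_detection_history()` returns a [detection_history].
#' @export
write_detection_history <- function(history, prefix) {
  occ <- sprintf("o%d", seq_len(history$K))
  ydf <- cbind(history$site, as.data.frame(history$y) |> stats::setNames(occ))
  edf <- cbind(history$site,
               as.data.frame(history$effort) |> stats::setNames(occ))
  write.csv(ydf, paste0(prefix, "_y.csv"), row.names = FALSE)
  write.csv(edf, paste0(prefix, "_effort.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_detection_history
#' @param occasion_length_days occasion length of the stored history.
#' @export
read_detection_history <- function(prefix, occasion_length_days = 15) {
  ydf <- read.csv(paste0(prefix, "_y.csv"))
  edf <- read.csv(paste0(prefix, "_effort.csv"))
  assemble_history_tables_(ydf, edf, occasion_length_days)
}

assemble_history_tables_ <- function(ydf, edf, occasion_length_days) {
  occ <- grep("^o[0-9]+$", names(ydf), value = TRUE)
  if (!length(occ)) stop_("no occasion columns (o1..oK) found")
  id_cols <- intersect(c("station_id", "year", "survey"), names(ydf))
  y <- as.matrix(ydf[occ]); storage.mode(y) <- "integer"
  if (is.null(edf)) {
    effort <- matrix(0L, nrow(y), ncol(y))
    effort[!is.na(y)] <- as.integer(occasion_length_days)
  } else {
    effort <- as.matrix(edf[occ]); storage.mode(effort) <- "integer"
  }
  dimnames(y) <- NULL; dimnames(effort) <- NULL
  new_detection_history(ydf[id_cols], y, effort, occasion_length_days)
}

#' Read a deposited detection-history spreadsheet
#'
#' Accepts a prebuilt sites x occasions detection matrix from an XLSX
#' workbook (e.g. a study's deposited supplementary dataset), bypassing the
#' history builder. Occasion columns are detected as `o1..oK` or taken as
#' all non-identifier columns. Effort defaults to the full occasion length
#' where `y` is observed unless a parallel effort sheet is given.
#'
#' @param path XLSX file path.
#' @param sheet sheet name or index.
#' @param effort_sheet optional sheet holding the parallel effort matrix.
#' @param occasion_length_days occasion length represented by the matrix.
#' @return a [detection_history].
#' @export
read_detection_matrix_xlsx <- function(path, sheet = 1, effort_sheet = NULL,
                                       occasion_length_days = 15) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop_("reading XLSX requires the 'readxl' package")
  ydf <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  names(ydf) <- sub("^[Oo]cc(asion)?[._ ]?", "o", names(ydf))
  if (!any(grepl("^o[0-9]+$", names(ydf)))) {
    id_cols <- intersect(c("station_id", "year", "survey"), names(ydf))
    occ_cols <- setdiff(names(ydf), id_cols)
    names(ydf)[match(occ_cols, names(ydf))] <- sprintf("o%d",
                                                       seq_along(occ_cols))
  }
  edf <- if (!is.null(effort_sheet))
    as.data.frame(readxl::read_excel(path, sheet = effort_sheet)) else NULL
  if (!"station_id" %in% names(ydf))
    ydf$station_id <- sprintf("S%04d", seq_len(nrow(ydf)))
  if (!"year" %in% names(ydf)) ydf$year <- 1L
  assemble_history_tables_(ydf, edf, occasion_length_days)
}

#' Read a deposited site-covariate spreadsheet
#'
#' Thin XLSX reader for deposited covariate tables; reports via
#' `attr(, "standardized")` whether the stored values appear already
#' z-scored (see [read_covariates()]).
#'
#' @param path XLSX file path.
#' @param sheet sheet name or index.
#' @return covariate data frame.
#' @export
read_covariates_xlsx <- function(path, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop_("reading XLSX requires the 'readxl' package")
  flag_standardized_(as.data.frame(readxl::read_excel(path, sheet = sheet)))
}
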