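# Detection/effort history construction from raw camera-trap tables.

#' Detection history container
#'
#' Holds the stacked sites x occasions detection matrix `y` (0/1/NA), the
#' parallel effort matrix (active days per occasion, 0 where `y` is NA), and
#' the site index (one row per camera-year). Constructed by
#' [build_detection_history()] or [simulate_detection_history()].
#'
#' @param site data frame with at least `station_id` and `year` (and
#'   optionally `survey`), one row per stacked site.
#' @param y integer matrix sites x K with entries 0, 1 or NA.
#' @param effort integer matrix sites x K of active days per occasion.
#' @param occasion_length_days occasion length in days.
#' @return an object of class `detection_history`.
#' @export
new_detection_history <- function(site, y, effort, occasion_length_days) {
  y <- as.matrix(y); effort <- as.matrix(effort)
  if (!all(dim(y) == dim(effort)))
    stop_("y and effort must have identical dimensions")
  if (nrow(y) != nrow(site))
    stop_("site table and matrices disagree on the number of sites")
  if (any(!is.na(y) & !(y %in% c(0L, 1L))))
    stop_("y entries must be 0, 1 or NA")
  if (any(is.na(y) != (effort == 0)))
    stop_("missingness pattern violated: y must be NA exactly where effort is 0")
  if (nrow(y) > 0 && any(rowSums(effort > 0) == 0))
    stop_("every site must have at least one surveyed occasion")
  if (anyDuplicated(paste(site$station_id, site$year)))
    stop_("site index must be unique on (station_id, year)")
  structure(list(site = site, y = y, effort = effort,
                 occasion_length_days = as.integer(occasion_length_days),
                 K = ncol(y)),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  nd <- sum(x$y == 1L, na.rm = TRUE)
  cat(sprintf(
    "<detection_history> %d sites x %d occasions (%d d), %d detections, %d trap-nights\n",
    nrow(x$y), x$K, x$occasion_length_days, nd, sum(x$effort)))
  invisible(x)
}

#' Filter records to temporally independent events
#'
#' Within each station, records are scanned in time order and any record
#' closer than `interval_minutes` to the previously *retained* record is
#' dropped, the standard camera-trap convention for declaring events
#' independent. Independence is assessed per station; simultaneous records
#' at different stations are always kept.
#'
#' @param records data frame with `station_id` and `timestamp` (POSIXct or
#'   parseable character).
#' @param interval_minutes non-negative independence window; 0 keeps all
#'   records.
#' @return the filtered record table, sorted by station and time.
#' @export
filter_independent_records <- function(records, interval_minutes = 30) {
  assert_number(interval_minutes, "interval_minutes", lower = 0)
  records <- check_records(records)
  if (nrow(records) == 0L || interval_minutes == 0) return(records)
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$station_id),
                        function(idx) {
    ts <- as.numeric(records$timestamp[idx])
    sel <- logical(length(idx))
    last <- -Inf
    for (j in seq_along(idx)) {
      if (ts[j] - last >= interval_minutes * 60) {
        sel[j] <- TRUE
        last <- ts[j]
      }
    }
    idx[sel]
  }), use.names = FALSE)
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_records <- function(records) {
  if (!all(c("station_id", "timestamp") %in% names(records)))
    stop_("records need columns 'station_id' and 'timestamp'")
  if (!inherits(records$timestamp, "POSIXct")) {
    ts <- as.POSIXct(records$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d"))
    if (anyNA(ts)) stop_("unparseable record timestamps")
    records$timestamp <- ts
  }
  if (any(!nzchar(records$station_id))) stop_("empty station_id in records")
  records <- records[order(records$station_id, records$timestamp), ,
                     drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Stack deployments into camera-year sites
#'
#' Implements the stacked site-year design: a deployment spanning a calendar
#' year boundary is split at the boundary so each piece lies in one year,
#' and each unique (station, year) combination becomes one sampling site.
#'
#' @param deployments data frame with `station_id`, `start_date`, `end_date`
#'   (Date or parseable character) and optionally `survey`.
#' @return deployment table with one row per (station, year), columns
#'   `station_id`, `start_date`, `end_date`, `survey`, `year`.
#' @export
stack_site_years <- function(deployments) {
  d <- deployments
  if (!all(c("station_id", "start_date", "end_date") %in% names(d)))
    stop_("deployments need station_id, start_date, end_date")
  if (nrow(d) == 0L)
    return(data.frame(station_id = character(), start_date = as.Date(character()),
                      end_date = as.Date(character()), survey = character(),
                      year = integer(), stringsAsFactors = FALSE))
  d$start_date <- as.Date(d$start_date)
  d$end_date <- as.Date(d$end_date)
  if (anyNA(d$start_date) || anyNA(d$end_date))
    stop_("unparseable deployment dates")
  if (!"survey" %in% names(d)) d$survey <- NA_character_
  pieces <- lapply(seq_len(nrow(d)), function(i) {
    s <- d$start_date[i]; e <- d$end_date[i]
    if (e < s) return(NULL)
    y1 <- as.integer(format(s, "%Y")); y2 <- as.integer(format(e, "%Y"))
    yrs <- y1:y2
    data.frame(
      station_id = d$station_id[i],
      start_date = pmax(s, as.Date(sprintf("%d-01-01", yrs))),
      end_date = pmin(e, as.Date(sprintf("%d-12-31", yrs))),
      survey = d$survey[i],
      year = yrs,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  key <- paste(out$station_id, out$year)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_("overlapping deployments for the same station-year: %s",
          paste(dup, collapse = "; "))
  }
  out <- out[order(out$station_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the detection/effort history matrix
#'
#' Converts independent records and stacked deployments into a
#' sites x occasions detection matrix. For each stacked site, occasions are
#' consecutive `occasion_length`-day bins anchored at the deployment start
#' and truncated at `min(deployment end, start + max_days - 1)` to respect
#' the closure window. `y[i,t]` is 1 if at least one record falls in bin t,
#' 0 if the bin was surveyed without a record, and NA where effort is 0;
#' `effort[i,t]` counts the active days in the bin. All rows are padded to
#' `K = floor(max_days / occasion_length)` columns.
#'
#' @param records independent detection records (`station_id`, `timestamp`).
#' @param deployments deployment table; stacked internally with
#'   [stack_site_years()].
#' @param occasion_length days per occasion (default 15).
#' @param max_days closure window in days (default 120).
#' @return a [detection_history] object.
#' @export
build_detection_history <- function(records, deployments,
                                    occasion_length = 15, max_days = 120) {
  assert_number(occasion_length, "occasion_length", lower = 1)
  assert_number(max_days, "max_days", lower = occasion_length)
  records <- check_records(records)
  dep <- stack_site_years(deployments)

  zero_len <- dep$end_date < dep$start_date
  if (any(zero_len)) {
    warning(sprintf("dropping %d zero-length deployment(s)", sum(zero_len)),
            call. = FALSE)
    dep <- dep[!zero_len, , drop = FALSE]
  }
  n <- nrow(dep)
  K <- floor(max_days / occasion_length)
  y <- matrix(NA_integer_, n, K)
  effort <- matrix(0L, n, K)

  rec_by_station <- split(as.numeric(as.Date(records$timestamp, tz = "UTC")),
                          records$station_id)
  used <- integer(0)
  rec_dates_all <- as.numeric(as.Date(records$timestamp, tz = "UTC"))

  for (i in seq_len(n)) {
    ws <- as.numeric(dep$start_date[i])
    we <- min(as.numeric(dep$end_date[i]), ws + max_days - 1)
    rd <- rec_by_station[[dep$station_id[i]]] %||% numeric(0)
    inside <- rd[rd >= ws & rd <= we]
    for (t in seq_len(K)) {
      bs <- ws + (t - 1) * occasion_length
      be <- min(bs + occasion_length - 1, we)
      e <- max(0, be - bs + 1)
      effort[i, t] <- as.integer(e)
      if (e > 0) y[i, t] <- as.integer(any(inside >= bs & inside <= be))
    }
    # mark records of this station lying in any deployment of it
    used <- c(used, which(records$station_id == dep$station_id[i] &
                            rec_dates_all >= as.numeric(dep$start_date[i]) &
                            rec_dates_all <= as.numeric(dep$end_date[i])))
  }
  orphan <- setdiff(seq_len(nrow(records)), unique(used))
  if (length(orphan))
    warning(sprintf(
      "%d record(s) fall outside every deployment of their station and were dropped",
      length(orphan)), call. = FALSE)

  empty_rows <- rowSums(effort > 0) == 0
  if (any(empty_rows)) {
    warning(sprintf("dropping %d site(s) with no surveyed occasion",
                    sum(empty_rows)), call. = FALSE)
    dep <- dep[!empty_rows, , drop = FALSE]
    y <- y[!empty_rows, , drop = FALSE]
    effort <- effort[!empty_rows, , drop = FALSE]
  }
  site <- dep[, intersect(c("station_id", "year", "survey"), names(dep)),
              drop = FALSE]
  rownames(site) <- NULL
  new_detection_history(site, y, effort, occasion_length)
}

#' Summarize survey effort and detections
#'
#' @param history a [detection_history].
#' @return list with `total_trap_nights` (sum of the effort matrix),
#'   `n_sites`, `n_detections` (cells with y = 1), `mean_effort` and
#'   `sd_effort` over surveyed occasions, and `naive_occupancy` (share of
#'   sites with at least one detection).
#' @export
summarize_effort <- function(history) {
  if (!inherits(history, "detection_history"))
    stop_("'history' must be a detection_history")
  eff <- history$effort
  active <- eff > 0
  n <- nrow(eff)
  list(
    total_trap_nights = sum(eff),
    n_sites = n,
    n_detections = sum(history$y == 1L, na.rm = TRUE),
    mean_effort = if (any(active)) mean(eff[active]) else 0,
    sd_effort = if (sum(active) > 1) sd(eff[active]) else 0,
    naive_occupancy = if (n) mean(rowSums(history$y == 1L, na.rm = TRUE) > 0)
                      else 0
  )
}
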