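# Record filtering, site-year stacking, history building, effort
# bookkeeping.

rec <- function(station, times) {
  data.frame(station_id = station,
             timestamp = as.POSIXct(times, tz = "UTC"),
             stringsAsFactors = FALSE)
}

test_that("independence filter keeps the first record of each burst", {
  r <- rec("A", c("2021-03-01 10:00:00", "2021-03-01 10:10:00",
                  "2021-03-01 10:40:00"))
  out <- filter_independent_records(r, 30)
  expect_equal(format(out$timestamp, "%H:%M"), c("10:00", "10:40"))

  expect_equal(nrow(filter_independent_records(r, 0)), 3L)
  expect_error(filter_independent_records(r, -5), "interval")

  # independence is assessed per station
  r2 <- rec(c("A", "B"), rep("2021-03-01 10:00:00", 2))
  expect_equal(nrow(filter_independent_records(r2, 30)), 2L)
})

test_that("stacking splits deployments at calendar-year boundaries", {
  d <- data.frame(station_id = "A", start_date = "2020-12-01",
                  end_date = "2021-01-31", survey = "OC")
  out <- stack_site_years(d)
  expect_equal(out$year, c(2020L, 2021L))
  expect_equal(out$start_date, as.Date(c("2020-12-01", "2021-01-01")))
  expect_equal(out$end_date, as.Date(c("2020-12-31", "2021-01-31")))

  d2 <- data.frame(station_id = "A", start_date = "2021-02-01",
                   end_date = "2021-04-30", survey = "OC")
  out2 <- stack_site_years(d2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$start_date, as.Date("2021-02-01"))

  expect_equal(nrow(stack_site_years(d[0, ])), 0L)

  dup <- rbind(d2, data.frame(station_id = "A", start_date = "2021-06-01",
                              end_date = "2021-07-01", survey = "OC"))
  expect_error(stack_site_years(dup), "overlapping")
})

test_that("45-day deployment with records on days 3 and 20 bins correctly", {
  r <- rec("A", c("2021-01-03 08:00:00", "2021-01-20 19:30:00"))
  d <- data.frame(station_id = "A", start_date = "2021-01-01",
                  end_date = "2021-02-14", survey = "OC")
  h <- build_detection_history(r, d)
  expect_equal(as.vector(h$y[1, ]), c(1L, 1L, 0L, NA, NA, NA, NA, NA))
  expect_equal(as.vector(h$effort[1, ]), c(15L, 15L, 15L, 0L, 0L, 0L, 0L, 0L))
})

test_that("long deployments are truncated to the 120-day closure window", {
  d <- data.frame(station_id = "A", start_date = "2020-01-01",
                  end_date = "2020-07-18", survey = "OC")   # 200 days
  h <- build_detection_history(rec("A", "2020-06-01 12:00:00")[0, ], d)
  expect_equal(h$K, 8L)
  expect_equal(as.vector(h$effort[1, ]), rep(15L, 8))
  expect_equal(as.vector(h$y[1, ]), rep(0L, 8))
})

test_that("records outside every deployment are dropped with a warning", {
  r <- rec("A", c("2021-01-05 10:00:00", "2021-09-01 10:00:00"))
  d <- data.frame(station_id = "A", start_date = "2021-01-01",
                  end_date = "2021-01-30", survey = "OC")
  expect_warning(h <- build_detection_history(r, d), "outside every deployment")
  expect_equal(sum(h$y, na.rm = TRUE), 1L)
})

test_that("effort bookkeeping is exact on simulated data", {
  cfg <- sim_config(n_stations = 50, years_per_station = 2, seed = 9)
  study <- simulate_study(cfg)
  s <- summarize_effort(study$history)
  dep_days <- sum(as.integer(study$deployments$end_date -
                               study$deployments$start_date) + 1L)
  expect_identical(s$total_trap_nights, dep_days)
  expect_lte(s$total_trap_nights, s$n_sites * 120)
  # full-effort site contributes 8 x 15 trap-nights
  full <- manual_history(matrix(0L, 1, 8), matrix(15L, 1, 8))
  expect_equal(summarize_effort(full)$total_trap_nights, 120L)
  # empty history
  empty <- manual_history(matrix(0L, 0, 8), matrix(15L, 0, 8))
  expect_equal(summarize_effort(empty)$total_trap_nights, 0L)
  expect_equal(summarize_effort(empty)$naive_occupancy, 0)
})

test_that("missingness and detection cells are mutually consistent", {
  cfg <- sim_config(n_stations = 60, years_per_station = 1, seed = 10)
  h <- simulate_detection_history(simulate_covariates(cfg), cfg)
  expect_true(all(is.na(h$y) == (h$effort == 0)))
  expect_true(all(h$effort[which(h$y == 1L)] > 0))
})

test_that("rebuilding from simulated records reproduces the matrix exactly", {
  for (seed in c(2, 21)) {
    cfg <- sim_config(n_stations = 40, years_per_station = 2, seed = seed)
    study <- simulate_study(cfg)
    h2 <- build_detection_history(study$records, study$deployments)
    expect_identical(h2$y, study$history$y)
    expect_identical(h2$effort, study$history$effort)
    expect_identical(h2$site$station_id, study$history$site$station_id)
  }
})
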