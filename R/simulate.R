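# Synthetic camera-trap study generator.
#
# Emulates the statistical structure of a stacked camera-year occupancy
# survey in montane forest: station-level site covariates with realistic
# marginal moments, a 5-database survey factor, deployments of varying
# length binned into 15-day occasions, and detection histories generated
# from the single-season occupancy model itself (latent habitat use z,
# imperfect detection p). Latent states are exposed for recovery tests but
# are never an input to the fitting code.

# Table-1-scale marginal moments of the six site covariates
.default_cov_means <- c(
  tree_cover = 86.13, dist_water = 485.4, dist_road = 2513.36,
  elevation = 2489.4, ruggedness = 25.43, dist_settlement = 4875.55
)
.default_cov_sds <- c(
  tree_cover = 14.26, dist_water = 365.73, dist_road = 2837.4,
  elevation = 516.97, ruggedness = 12.08, dist_settlement = 4314.09
)
.cov_bounds <- list(
  tree_cover = c(0, 100), dist_water = c(0, Inf), dist_road = c(0, Inf),
  elevation = c(0, Inf), ruggedness = c(0, Inf), dist_settlement = c(0, Inf)
)

#' Generating parameters for the synthetic occupancy study
#'
#' Defines the true parameter values used by [simulate_detection_history()].
#' Slopes act on internally z-scored covariates, so they are effects per
#' covariate standard deviation, matching how the model is fitted. Defaults
#' are the best-supported habitat-use effects for a montane small-felid
#' survey (tree cover 0.69, elevation 0.68, distance to water -0.42, terrain
#' ruggedness 0.23; road and settlement distances null), an occupancy
#' intercept calibrated so mean habitat use is about 0.30, a detection
#' intercept giving per-occasion detection about 0.09, and an effort slope
#' of 0.34 per SD of active-days.
#'
#' @param beta0 occupancy intercept, logit scale.
#' @param beta named vector of occupancy slopes per covariate SD.
#' @param sigma_station SD (>= 0) of the station-level random intercept.
#' @param gamma0 detection intercept, logit scale.
#' @param gamma_effort detection slope per SD of per-occasion effort.
#' @param survey_effects named vector of detection offsets per survey level;
#'   the reference level must be 0 (all-zero is the default: no survey
#'   heterogeneity).
#' @return an object of class `true_params`.
#' @export
true_params <- function(beta0 = -1.03,
                        beta = c(tree_cover = 0.69, elevation = 0.68,
                                 dist_water = -0.42, ruggedness = 0.23,
                                 dist_road = 0, dist_settlement = 0),
                        sigma_station = 0.5,
                        gamma0 = -2.31,
                        gamma_effort = 0.34,
                        survey_effects = c(MV = 0, NAI = 0, CNR = 0,
                                           QERC = 0, OC = 0)) {
  assert_number(beta0, "beta0")
  assert_number(gamma0, "gamma0")
  assert_number(gamma_effort, "gamma_effort")
  assert_number(sigma_station, "sigma_station", lower = 0)
  if (length(beta) && is.null(names(beta)))
    stop_("'beta' must be a named vector of covariate slopes")
  if (length(survey_effects) && is.null(names(survey_effects)))
    stop_("'survey_effects' must be named by survey level")
  if (length(survey_effects) && min(abs(survey_effects)) > 0)
    stop_("at least one survey level must have effect 0 (the reference)")
  structure(list(beta0 = beta0, beta = beta, sigma_station = sigma_station,
                 gamma0 = gamma0, gamma_effort = gamma_effort,
                 survey_effects = survey_effects),
            class = "true_params")
}

#' Configuration of the synthetic camera-trap study
#'
#' Study dimensions and covariate marginals for the generator. The defaults
#' describe a study of 204 stations each run for 3 consecutive years (612
#' stacked camera-year sites), up to 8 occasions of 15 days, deployment
#' lengths uniform on 75--120 days (about 59,700 trap-nights in total, with
#' 5--8 surveyed occasions per site), and site covariates drawn from
#' moment-matched truncated-normal or gamma marginals.
#'
#' @param n_stations number of camera stations (>= 0).
#' @param years_per_station consecutive years each station is deployed.
#' @param n_occasions maximum occasions per site.
#' @param occasion_length_days days per occasion.
#' @param covariate_means,covariate_sds named marginal moments of the site
#'   covariates (SDs must be positive).
#' @param survey_levels labels of the survey databases; one is assigned to
#'   each station uniformly at random.
#' @param deployment_days length-2 integer range of deployment durations in
#'   days; durations are drawn uniformly from this range.
#' @param first_year first calendar year of the study.
#' @param true_params a [true_params()] object.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_stations = 204,
                       years_per_station = 3,
                       n_occasions = 8,
                       occasion_length_days = 15,
                       covariate_means = .default_cov_means,
                       covariate_sds = .default_cov_sds,
                       survey_levels = c("MV", "NAI", "CNR", "QERC", "OC"),
                       deployment_days = c(75, 120),
                       first_year = 2019,
                       true_params = camoccu::true_params(),
                       seed = 1) {
  assert_number(n_stations, "n_stations", lower = 0)
  assert_number(years_per_station, "years_per_station", lower = 1)
  assert_number(n_occasions, "n_occasions", lower = 1)
  assert_number(occasion_length_days, "occasion_length_days", lower = 1)
  assert_number(seed, "seed", lower = -2^31 + 10, upper = 2^31 - 10)
  if (is.null(names(covariate_means)) || is.null(names(covariate_sds)) ||
      !setequal(names(covariate_means), names(covariate_sds)))
    stop_("covariate_means and covariate_sds must share the same names")
  if (any(covariate_sds <= 0))
    stop_("all covariate SDs must be positive (offending: %s)",
          paste(names(covariate_sds)[covariate_sds <= 0], collapse = ", "))
  if (length(deployment_days) != 2L || any(deployment_days < 1) ||
      deployment_days[1] > deployment_days[2] ||
      deployment_days[2] > n_occasions * occasion_length_days)
    stop_("deployment_days must be an increasing range within [1, %d]",
          n_occasions * occasion_length_days)
  if (!inherits(true_params, "true_params"))
    stop_("'true_params' must be created with true_params()")
  structure(list(
    n_stations = as.integer(n_stations),
    years_per_station = as.integer(years_per_station),
    n_occasions = as.integer(n_occasions),
    occasion_length_days = as.integer(occasion_length_days),
    covariate_means = covariate_means,
    covariate_sds = covariate_sds[names(covariate_means)],
    survey_levels = survey_levels,
    deployment_days = as.integer(deployment_days),
    first_year = as.integer(first_year),
    true_params = true_params,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d stations x %d yr, K=%d occasions of %d d, seed %d\n",
    x$n_stations, x$years_per_station, x$n_occasions,
    x$occasion_length_days, x$seed))
  invisible(x)
}

#' Simulate stacked-site covariates
#'
#' Draws station-level site covariates from independent truncated normal
#' distributions whose truncated moments match `covariate_means`/`_sds`
#' (tree cover bounded to \[0, 100\], distances and elevation to \[0, Inf)),
#' assigns each station a survey label uniformly at random, and replicates
#' station rows across years to form one row per stacked camera-year site.
#'
#' @param cfg a [sim_config()].
#' @return a data frame with columns `station_id`, `year`, `survey` and one
#'   column per covariate; zero rows (full schema) when `n_stations = 0`.
#' @export
simulate_covariates <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_("'cfg' must be a sim_config")
  covs <- names(cfg$covariate_means)
  empty <- data.frame(station_id = character(), year = integer(),
                      survey = character(), stringsAsFactors = FALSE)
  for (v in covs) empty[[v]] <- numeric()
  if (cfg$n_stations == 0L) return(empty)

  with_seed_(cfg$seed, {
    station_id <- sprintf("ST%04d", seq_len(cfg$n_stations))
    survey <- sample(cfg$survey_levels, cfg$n_stations, replace = TRUE)
    vals <- lapply(covs, function(v) {
      b <- .cov_bounds[[v]] %||% c(-Inf, Inf)
      m <- cfg$covariate_means[[v]]; s <- cfg$covariate_sds[[v]]
      if (is.infinite(b[2]) && b[1] == 0 && m / s < 6) {
        # strongly truncated non-negative covariate: a left-truncated normal
        # cannot reach sd ~ mean, so use a moment-matched gamma (right-skewed,
        # as distance-to-feature covariates are)
        rgamma(cfg$n_stations, shape = (m / s)^2, rate = m / s^2)
      } else {
        par <- truncnorm_match(m, s, b[1], b[2])
        rtruncnorm_(cfg$n_stations, par["mu"], par["sigma"], b[1], b[2])
      }
    })
    names(vals) <- covs
    st <- data.frame(station_id = station_id, survey = survey,
                     stringsAsFactors = FALSE)
    for (v in covs) st[[v]] <- vals[[v]]
    idx <- rep(seq_len(cfg$n_stations), each = cfg$years_per_station)
    out <- st[idx, , drop = FALSE]
    out$year <- rep(cfg$first_year + seq_len(cfg$years_per_station) - 1L,
                    times = cfg$n_stations)
    rownames(out) <- NULL
    out[, c("station_id", "year", "survey", covs)]
  })
}

# deployment interval per stacked site; each interval is kept inside its
# calendar year so site-years never need splitting
sim_deployments_ <- function(cov, cfg) {
  n <- nrow(cov)
  with_seed_(cfg$seed + 1L, {
    len <- cfg$deployment_days[1] +
      sample.int(cfg$deployment_days[2] - cfg$deployment_days[1] + 1L,
                 n, replace = TRUE) - 1L
    offset <- vapply(len, function(l) sample.int(365 - l + 1L, 1L) - 1L,
                     integer(1))
    start <- as.Date(sprintf("%d-01-01", cov$year)) + offset
    data.frame(station_id = cov$station_id,
               start_date = start,
               end_date = start + len - 1L,
               survey = cov$survey,
               year = cov$year,
               stringsAsFactors = FALSE)
  })
}

#' Simulate detection histories from the occupancy model
#'
#' Internally z-scores the modeled covariates, draws station random
#' intercepts, latent habitat-use states `z ~ Bernoulli(psi)` and occasion
#' detections `y ~ Bernoulli(z * p)`, where `logit(psi)` is the occupancy
#' linear predictor and `logit(p)` includes the z-scored per-occasion effort
#' and the survey effect. Effort per occasion follows each site's deployment
#' length (15-day bins, trailing occasion possibly partial, unused occasions
#' missing).
#'
#' @param cov covariate table from [simulate_covariates()].
#' @param cfg the [sim_config()] used to create `cov`.
#' @return a [detection_history] object. The generating truth is attached as
#'   `attr(, "truth")` (list with `z`, `psi`, `p`, `alpha`) for recovery
#'   tests only.
#' @export
simulate_detection_history <- function(cov, cfg) {
  if (!inherits(cfg, "sim_config")) stop_("'cfg' must be a sim_config")
  tp <- cfg$true_params
  missing_cov <- setdiff(names(tp$beta), names(cov))
  if (length(missing_cov))
    stop_("true_params slopes name covariates absent from the table: %s",
          paste(missing_cov, collapse = ", "))
  n <- nrow(cov)
  K <- cfg$n_occasions
  len <- cfg$occasion_length_days
  dep <- sim_deployments_(cov, cfg)
  dep_len <- as.integer(dep$end_date - dep$start_date) + 1L

  # effort: consecutive bins from deployment start, truncated at the end
  effort <- vapply(seq_len(K), function(t)
    pmin(pmax(dep_len - (t - 1L) * len, 0L), len), integer(n))
  effort <- matrix(effort, nrow = n, ncol = K)

  with_seed_(cfg$seed + 2L, {
    # z-score modeled covariates with their own sample moments
    Z <- vapply(names(tp$beta), function(v) {
      x <- cov[[v]]
      (x - mean(x)) / sd(x)
    }, numeric(n))
    Z <- matrix(Z, nrow = n)
    eta_psi <- tp$beta0 + drop(Z %*% tp$beta)
    stations <- unique(cov$station_id)
    alpha <- rnorm(length(stations), 0, tp$sigma_station)
    names(alpha) <- stations
    eta_psi <- eta_psi + alpha[cov$station_id]
    psi <- plogis(eta_psi)
    z <- rbinom(n, 1L, psi)

    active <- effort > 0
    eff_z <- effort
    eff_z[!active] <- NA_integer_
    e_mean <- mean(eff_z, na.rm = TRUE)
    e_sd <- sd(eff_z[active])
    if (!is.finite(e_sd) || e_sd == 0) e_sd <- 1
    effz <- (effort - e_mean) / e_sd

    sv <- tp$survey_effects[cov$survey]
    sv[is.na(sv)] <- 0
    p <- plogis(tp$gamma0 + tp$gamma_effort * effz +
                  matrix(sv, nrow = n, ncol = K))
    y <- matrix(rbinom(n * K, 1L, rep(z, K) * as.vector(p)), n, K)
    y[!active] <- NA_integer_
    p[!active] <- NA_real_

    site <- cov[, c("station_id", "year", "survey"), drop = FALSE]
    h <- new_detection_history(site, y, effort, len)
    attr(h, "truth") <- list(z = z, psi = psi, p = p, alpha = alpha)
    h
  })
}

#' Simulate raw records and deployment tables
#'
#' Produces the raw inputs of the detection-history builder: one deployment
#' interval per stacked site and timestamped records placed uniformly inside
#' the active days of each occasion flagged as a detection by
#' [simulate_detection_history()]. Rebuilding the history from these tables
#' with [build_detection_history()] reproduces the simulated matrix exactly.
#'
#' @inheritParams simulate_detection_history
#' @return list with elements `records` (station_id, timestamp) and
#'   `deployments` (station_id, start_date, end_date, survey, year); the
#'   generating [detection_history] is attached as `attr(, "history")`.
#' @export
simulate_records <- function(cov, cfg) {
  h <- simulate_detection_history(cov, cfg)
  dep <- sim_deployments_(cov, cfg)
  len <- cfg$occasion_length_days
  hits <- which(h$y == 1L, arr.ind = TRUE)
  with_seed_(cfg$seed + 3L, {
    if (nrow(hits)) {
      i <- hits[, 1]; t <- hits[, 2]
      day_in_occ <- vapply(h$effort[hits], function(e) sample.int(e, 1L) - 1L,
                           integer(1))
      day <- (t - 1L) * len + day_in_occ
      secs <- floor(runif(nrow(hits), 0, 86400))
      ts <- as.POSIXct(dep$start_date[i], tz = "UTC") + day * 86400 + secs
      records <- data.frame(station_id = dep$station_id[i],
                            timestamp = ts, stringsAsFactors = FALSE)
      records <- records[order(records$station_id, records$timestamp), ,
                         drop = FALSE]
      rownames(records) <- NULL
    } else {
      records <- data.frame(station_id = character(),
                            timestamp = as.POSIXct(character(), tz = "UTC"),
                            stringsAsFactors = FALSE)
    }
    out <- list(records = records, deployments = dep)
    attr(out, "history") <- h
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_covariates()],
#' [simulate_detection_history()] and [simulate_records()] under one
#' configuration.
#'
#' @param cfg a [sim_config()].
#' @return list with `covariates`, `history`, `records`, `deployments`,
#'   `truth`.
#' @export
simulate_study <- function(cfg) {
  cov <- simulate_covariates(cfg)
  rec <- simulate_records(cov, cfg)
  h <- attr(rec, "history")
  list(covariates = cov, history = h, records = rec$records,
       deployments = rec$deployments, truth = attr(h, "truth"))
}
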