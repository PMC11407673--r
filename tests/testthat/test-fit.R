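# MCMC fitting: dimensions, reproducibility, convergence checking,
# posterior behaviour on informative and degenerate data.

test_that("fit dimensions follow the chains/iterations/burn-in contract", {
  study <- small_study(n_stations = 40, seed = 41)
  spec <- occu_spec("tree_cover", "effort", FALSE)
  fit <- quick_fit(spec, study, n_iter = 800)
  expect_equal(nrow(fit$draws), 2 * 800 / 2)
  expect_equal(ncol(fit$pointwise_loglik), nrow(fit$draws))
  expect_equal(nrow(fit$pointwise_loglik), nrow(study$history$y))
  expect_setequal(colnames(fit$draws),
                  c("beta0", "beta[tree_cover]", "gamma0", "gamma[effort]"))
  expect_true(all(is.finite(fit$pointwise_loglik)))
})

test_that("identical seeds reproduce the fit; different seeds do not", {
  study <- small_study(n_stations = 30, seed = 42)
  spec <- occu_spec("tree_cover", character(0), FALSE)
  f1 <- quick_fit(spec, study, n_iter = 600, seed = 7)
  f2 <- quick_fit(spec, study, n_iter = 600, seed = 7)
  f3 <- quick_fit(spec, study, n_iter = 600, seed = 8)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a strong simulated effect is recovered within two posterior SDs", {
  study <- small_study(n_stations = 150, seed = 43,
                       beta = c(tree_cover = 1.5))
  spec <- occu_spec("tree_cover", "effort", FALSE)
  fit <- quick_fit(spec, study, n_iter = 2000)
  s <- summarize_posterior(fit)
  b <- s[s$parameter == "beta[tree_cover]", ]
  expect_lt(abs(b$mean - 1.5), 2 * b$sd)
  expect_gt(b$mean, 0)
})

test_that("all-zero data concentrate habitat use below one half", {
  y <- matrix(0L, 50, 8); eff <- matrix(15L, 50, 8)
  h <- manual_history(y, eff)
  cov <- data.frame(station_id = h$site$station_id, year = h$site$year,
                    tree_cover = rnorm(50, 85, 10))
  std <- z_transform(cov)
  # under the default uniform-on-probability intercept priors only a tiny
  # sliver of near-zero detectability lets psi float, so no-detection data
  # pin habitat use low
  spec <- occu_spec()
  expect_warning(
    fit <- fit_occupancy(spec, h, std, n_chains = 2, n_iter = 1500,
                         n_adapt = 200, seed = 2),
    "only detected or only undetected")
  psi_bar <- colMeans(camoccu:::psi_draws_(fit))
  expect_gt(mean(psi_bar < 0.5), 0.95)
})

test_that("convergence checking flags separated chains and degenerate draws", {
  # well-mixed fit passes
  study <- small_study(n_stations = 60, seed = 44)
  fit <- quick_fit(occu_spec("tree_cover", character(0), FALSE), study,
                   n_iter = 3000)
  conv <- check_convergence(fit)
  expect_true(conv$pass)
  expect_true(all(conv$rhat < 1.05))

  # chains in disjoint regions: Rhat far above threshold
  sep <- matrix(c(rnorm(400, 0, 0.05), rnorm(400, 10, 0.05)), ncol = 2)
  expect_gt(camoccu:::split_rhat(sep), 2)
  # constant chains are degenerate, not convergent
  expect_true(is.nan(camoccu:::split_rhat(matrix(1, 400, 2))))
  mock <- structure(list(n_chains = 2L, rhat = c(beta0 = NaN)),
                    class = "occu_fit")
  expect_false(check_convergence(mock)$pass)
  expect_equal(check_convergence(mock)$degenerate, "beta0")
  mock1 <- structure(list(n_chains = 1L, rhat = c(beta0 = 1)),
                     class = "occu_fit")
  expect_error(check_convergence(mock1), "2 chains")
})

test_that("posterior summaries expose derived habitat-use and detection", {
  study <- small_study(n_stations = 60, seed = 45)
  fit <- quick_fit(occu_spec("tree_cover", "effort", FALSE), study)
  s <- summarize_posterior(fit)
  expect_true(all(c("habitat_use", "detection") %in% s$parameter))
  expect_true(all(s$lo <= s$mean & s$mean <= s$hi))
  hu <- s[s$parameter == "habitat_use", ]
  expect_true(hu$mean > 0 && hu$mean < 1)
})

test_that("psi is monotone in a covariate with a positive slope, draw by draw", {
  study <- small_study(n_stations = 120, seed = 46,
                       beta = c(tree_cover = 2))
  fit <- quick_fit(occu_spec("tree_cover", character(0), FALSE), study,
                   n_iter = 1500)
  dr <- camoccu:::extract_draws(fit)
  pos <- dr$Beta[, 1] > 0
  expect_gt(mean(pos), 0.99)
  lo <- plogis(dr$beta0 + dr$Beta[, 1] * (-1))
  hi <- plogis(dr$beta0 + dr$Beta[, 1] * (+1))
  expect_true(all(hi[pos] >= lo[pos]))
})

test_that("year enters occupancy as a z-scored trend when requested", {
  cfg <- sim_config(n_stations = 30, years_per_station = 3, seed = 47)
  study <- simulate_study(cfg)
  std <- z_transform(study$covariates)
  fit <- fit_occupancy(occu_spec("year", "effort", FALSE), study$history,
                       std, n_chains = 2, n_iter = 600, n_adapt = 150,
                       seed = 1)
  expect_true("beta[year]" %in% colnames(fit$draws))
  expect_equal(unname(fit$design$year_params["mean"]),
               mean(study$history$site$year))
})
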