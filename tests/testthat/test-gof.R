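# MacKenzie-Bailey chi-square: exact statistic against brute force, edge
# cases, and rejection of a misspecified model.

test_that("a perfectly fitting single-occasion model gives X2 = 0", {
  y <- matrix(c(rep(1L, 5), rep(0L, 5)), ncol = 1)
  h <- manual_history(y, matrix(15L, 10, 1))
  cov <- data.frame(station_id = h$site$station_id, year = h$site$year)
  std <- z_transform(cov, columns = character(0))
  # psi = 1, p = 0.5 reproduces the empirical 5/5 split exactly
  out <- mb_chisq(list(beta0 = 40, gamma0 = 0), h, std, occu_spec())
  expect_equal(out$stat, 0, tolerance = 1e-6)
  expect_equal(sum(out$cohort_table$expected), 10, tolerance = 1e-6)
})

test_that("an impossible observed history blows the statistic up", {
  y <- matrix(c(1L, 0L), ncol = 1)
  h <- manual_history(y, matrix(15L, 2, 1))
  cov <- data.frame(station_id = h$site$station_id, year = h$site$year)
  std <- z_transform(cov, columns = character(0))
  # psi = p = 1: expected counts (2, 0); the observed all-zero site sits in
  # a cell the model calls (numerically) impossible
  out <- mb_chisq(list(beta0 = 40, gamma0 = 40), h, std, occu_spec())
  tab <- out$cohort_table
  expect_equal(tab$expected[tab$history == "1"], 2, tolerance = 1e-6)
  expect_equal(tab$observed[tab$history == "1"], 1)
  expect_gt(out$stat, 1e6)
})

test_that("the statistic equals brute-force enumeration over all histories", {
  set.seed(81)
  n <- 10; K <- 3
  cov <- data.frame(station_id = sprintf("S%02d", 1:n), year = 2020L,
                    tree_cover = rnorm(n, 80, 12))
  std <- z_transform(cov)
  eff <- matrix(15L, n, K)
  params <- list(beta0 = 0.2, beta = c(tree_cover = 0.8),
                 gamma0 = -0.5, gamma_effort = 0)
  x <- as.data.frame(std)$tree_cover
  psi <- plogis(params$beta0 + params$beta * x)
  p <- matrix(plogis(params$gamma0), n, K)
  y <- matrix(rbinom(n * K, 1L, rep(rbinom(n, 1, psi), K) * as.vector(p)),
              n, K)
  h <- new_detection_history(cov[, 1:2], y, eff, 15)

  # independent brute force: expected count of every one of the 8 histories
  hist_all <- as.matrix(expand.grid(rep(list(0:1), K)))
  E <- vapply(seq_len(nrow(hist_all)), function(r) {
    hh <- hist_all[r, ]
    sum(vapply(seq_len(n), function(i)
      enum_site_lik(psi[i], p[i, ], as.integer(hh)), numeric(1)))
  }, numeric(1))
  O <- vapply(seq_len(nrow(hist_all)), function(r)
    sum(apply(y, 1, function(row) all(row == hist_all[r, ]))), numeric(1))
  want <- sum((O - E)^2 / E)

  spec <- occu_spec("tree_cover", character(0), FALSE)
  got <- mb_chisq(params, h, std, spec, pool_floor = 0)
  expect_equal(got$stat, want, tolerance = 1e-8)
})

test_that("statistic and expected counts are invariant to site order", {
  set.seed(82)
  study <- small_study(n_stations = 40, seed = 82)
  params <- list(beta0 = -0.4, beta = c(tree_cover = 1), gamma0 = -1,
                 gamma_effort = 0.3)
  spec <- occu_spec("tree_cover", "effort", FALSE)
  s1 <- mb_chisq(params, study$history, study$std_cov, spec)
  perm <- sample(nrow(study$history$y))
  h2 <- history_subset(study$history, perm)
  s2 <- mb_chisq(params, h2, study$std_cov, spec)
  expect_equal(s1$stat, s2$stat, tolerance = 1e-9)
})

test_that("expected frequencies conserve each cohort's site count", {
  study <- small_study(n_stations = 60, seed = 83)
  params <- list(beta0 = 0, beta = c(tree_cover = 0.5), gamma0 = -1,
                 gamma_effort = 0.3)
  spec <- occu_spec("tree_cover", "effort", FALSE)
  out <- mb_chisq(params, study$history, study$std_cov, spec, pool_floor = 0)
  tab <- out$cohort_table
  sums <- as.numeric(tapply(tab$expected, tab$cohort, sum))
  counts <- as.numeric(tapply(tab$observed, tab$cohort, sum))
  expect_equal(sums, counts, tolerance = 1e-6)
})

test_that("posterior-predictive p-value detects unmodeled detection heterogeneity", {
  # strong survey effects in the data, none in the model
  study <- small_study(
    n_stations = 200, seed = 84, gamma0 = -1,
    survey_effects = c(MV = 2.5, NAI = -2.5, CNR = 2.5, QERC = -2.5, OC = 0))
  fit <- quick_fit(occu_spec("tree_cover", "effort", FALSE), study,
                   n_iter = 1200)
  g <- mb_gof(fit, n_sim = 120, seed = 5)
  expect_lt(g$p_value, 0.05)
  expect_true(all(g$sim_stats >= 0))
  expect_gt(g$observed_stat, 0)
})

test_that("small n_sim warns about p-value instability", {
  study <- small_study(n_stations = 30, seed = 85)
  fit <- quick_fit(occu_spec(), study, n_iter = 400)
  expect_warning(mb_gof(fit, n_sim = 50, seed = 1), "unstable")
})
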