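# The marginalized site likelihood against hand values and the
# latent-state enumeration oracle.

test_that("site marginal likelihood matches hand-computed mixtures", {
  expect_equal(site_marginal_likelihood(1, c(1, 1), c(1L, 1L)), 1)
  # psi = p = 0.5, all-zero history: 0.5 * 0.25 + 0.5
  expect_equal(site_marginal_likelihood(0.5, c(0.5, 0.5), c(0L, 0L)), 0.625)
  # missing occasion contributes no factor
  expect_equal(site_marginal_likelihood(0.5, c(0.5, 0.5), c(1L, NA)), 0.25)
  expect_error(site_marginal_likelihood(0.5, c(NA, 0.5), c(1L, 0L)),
               "inconsistent")
})

test_that("histories form a proper distribution: sum over all 2^K equals 1", {
  set.seed(11)
  for (K in 1:4) {
    psi <- runif(1)
    p <- runif(K)
    hist_all <- as.matrix(expand.grid(rep(list(0:1), K)))
    tot <- sum(apply(hist_all, 1, function(y)
      site_marginal_likelihood(psi, p, as.integer(y))))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("log-likelihood equals latent-state enumeration on small instances", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(2:3, 1); K <- sample(1:3, 1)
    cov <- data.frame(station_id = sprintf("S%d", 1:n), year = 2020L,
                      tree_cover = rnorm(n, 80, 10) + 1:n,
                      elevation = rnorm(n, 2500, 400) + 1:n)
    std <- z_transform(cov)
    eff <- matrix(sample(c(0L, 10L, 15L), n * K, TRUE,
                         prob = c(0.2, 0.3, 0.5)), n, K)
    if (any(rowSums(eff > 0) == 0)) next
    params <- list(beta0 = rnorm(1),
                   beta = c(tree_cover = rnorm(1), elevation = rnorm(1)),
                   gamma0 = rnorm(1), gamma_effort = rnorm(1))
    spec <- occu_spec(c("tree_cover", "elevation"), "effort", FALSE)

    # oracle's own psi/p from first principles
    X <- as.matrix(as.data.frame(std)[, c("tree_cover", "elevation")])
    psi <- plogis(params$beta0 + drop(X %*% params$beta))
    active <- eff > 0
    m <- mean(eff[active]); s <- if (sum(active) > 1) sd(eff[active]) else 1
    if (!is.finite(s) || s == 0) s <- 1
    pmat <- plogis(params$gamma0 + params$gamma_effort * (eff - m) / s)
    y <- matrix(NA_integer_, n, K)
    y[active] <- rbinom(sum(active), 1L, pmat[active])
    pmat[!active] <- NA_real_

    h <- new_detection_history(cov[, c("station_id", "year")], y, eff, 15)
    got <- occu_loglik(params, h, std, spec)
    expect_equal(got$total, enum_total_loglik(psi, pmat, y),
                 tolerance = 1e-10)
    want_pw <- vapply(seq_len(n), function(i)
      log(enum_site_lik(psi[i], pmat[i, ], y[i, ])), numeric(1))
    expect_equal(got$pointwise, want_pw, tolerance = 1e-10)
  }
})

test_that("a site observed on a single occasion reduces to the K=1 mixture", {
  cov <- data.frame(station_id = "S1", year = 2020L)
  std <- z_transform(cov, columns = character(0))
  h <- new_detection_history(cov, matrix(c(NA, 1L, NA), 1, 3),
                             matrix(c(0L, 15L, 0L), 1, 3), 15)
  got <- occu_loglik(list(beta0 = 0.3, gamma0 = -0.4), h, std, occu_spec())
  expect_equal(got$pointwise, log(plogis(0.3) * plogis(-0.4)),
               tolerance = 1e-12)
})

test_that("all-zero K=2 history at null parameters gives log 0.625 per site", {
  cov <- data.frame(station_id = "S1", year = 2020L, tree_cover = 1)
  std <- structure(cov, transform_params = list(),
                   class = c("std_covariates", "data.frame"))
  h <- new_detection_history(cov[, 1:2, drop = FALSE],
                             matrix(0L, 1, 2), matrix(15L, 1, 2), 15)
  got <- occu_loglik(list(beta0 = 0, gamma0 = 0), h, std, occu_spec())
  expect_equal(got$total, log(0.625), tolerance = 1e-10)
})

test_that("a zero random-intercept reproduces the fixed-effects likelihood", {
  study <- small_study(n_stations = 20, seed = 31)
  spec_re <- occu_spec("tree_cover", "effort", TRUE)
  spec_fx <- occu_spec("tree_cover", "effort", FALSE)
  alpha <- setNames(rep(0, 20), unique(study$covariates$station_id))
  params <- list(beta0 = -0.5, beta = c(tree_cover = 0.8), alpha = alpha,
                 sigma_station = 0, gamma0 = -1, gamma_effort = 0.3)
  ll_re <- occu_loglik(params, study$history, study$std_cov, spec_re)
  ll_fx <- occu_loglik(params, study$history, study$std_cov, spec_fx)
  expect_identical(ll_re$pointwise, ll_fx$pointwise)
})
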