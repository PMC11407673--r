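# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use brute-force enumeration, not the package's
# marginalized-likelihood code path.

# P(y | psi, p) for one site by summing over the latent state z in {0, 1}
enum_site_lik <- function(psi, p, y) {
  obs <- !is.na(y)
  p <- p[obs]; y <- y[obs]
  lik <- 0
  for (z in 0:1) {
    pz <- if (z == 1) psi else 1 - psi
    cond <- if (z == 1) prod(p^y * (1 - p)^(1 - y)) else as.numeric(all(y == 0))
    lik <- lik + pz * cond
  }
  lik
}

# joint likelihood of all sites by exhaustive enumeration over the 2^n
# latent-state vectors
enum_total_loglik <- function(psi, pmat, ymat) {
  n <- length(psi)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  total <- 0
  for (r in seq_len(nrow(states))) {
    z <- states[r, ]
    pr <- prod(ifelse(z == 1, psi, 1 - psi))
    for (i in seq_len(n)) {
      obs <- !is.na(ymat[i, ])
      yi <- ymat[i, obs]; pi <- pmat[i, obs]
      pr <- pr * if (z[i] == 1) prod(pi^yi * (1 - pi)^(1 - yi))
                 else as.numeric(all(yi == 0))
    }
    total <- total + pr
  }
  log(total)
}

# detection history from explicit matrices, for hand-built cases
manual_history <- function(y, effort, occasion_length = 15,
                           survey = NULL, years = NULL) {
  n <- nrow(y)
  site <- data.frame(station_id = sprintf("S%02d", seq_len(n)),
                     year = years %||% rep(2020L, n),
                     stringsAsFactors = FALSE)
  if (!is.null(survey)) site$survey <- survey
  new_detection_history(site, y, effort, occasion_length)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

history_subset <- function(h, idx) {
  new_detection_history(h$site[idx, , drop = FALSE],
                        h$y[idx, , drop = FALSE],
                        h$effort[idx, , drop = FALSE],
                        h$occasion_length_days)
}

# a small, detectable study for fast fitting tests
small_study <- function(n_stations = 80, seed = 1,
                        beta = c(tree_cover = 1), sigma = 0,
                        gamma0 = -1, gamma_effort = 0.34,
                        survey_effects = c(MV = 0, NAI = 0, CNR = 0,
                                           QERC = 0, OC = 0), ...) {
  cfg <- sim_config(
    n_stations = n_stations, years_per_station = 1,
    true_params = true_params(beta0 = 0, beta = beta, sigma_station = sigma,
                              gamma0 = gamma0, gamma_effort = gamma_effort,
                              survey_effects = survey_effects),
    seed = seed, ...)
  study <- simulate_study(cfg)
  study$std_cov <- z_transform(study$covariates)
  study
}

quick_fit <- function(spec, study, n_iter = 1200, seed = 1, ...) {
  fit_occupancy(spec, study$history, study$std_cov, n_chains = 2,
                n_iter = n_iter, n_adapt = 250, seed = seed, ...)
}
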