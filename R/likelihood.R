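# Single-season occupancy likelihood with the latent state marginalized.
#
# A site's contribution mixes the two latent states: with probability psi
# the species uses the site and each surveyed occasion is an independent
# Bernoulli(p_t) detection trial; with probability 1 - psi it does not and
# an all-zero history is observed with certainty. Missing occasions (zero
# effort) contribute no factor.

#' Marginal likelihood of one site's detection history
#'
#' Computes
#' \deqn{\psi \prod_{t \in obs} p_t^{y_t} (1-p_t)^{1-y_t} +
#'       (1-\psi)\,[\text{all observed } y_t = 0]}
#' where the product runs over non-missing occasions.
#'
#' @param psi occupancy (habitat-use) probability in \[0, 1\].
#' @param p vector of per-occasion detection probabilities.
#' @param y detection history: 0, 1 or NA per occasion (NA = not surveyed).
#' @return the marginal probability of `y`.
#' @export
site_marginal_likelihood <- function(psi, p, y) {
  assert_number(psi, "psi", lower = 0, upper = 1)
  if (length(p) != length(y))
    stop_("p and y must have the same length")
  obs <- !is.na(y)
  if (any(obs & is.na(p)))
    stop_("inconsistent input: observed y where detection probability is missing")
  p <- p[obs]; y <- y[obs]
  if (any(p < 0 | p > 1)) stop_("detection probabilities must lie in [0, 1]")
  det_prob <- prod(ifelse(y == 1, p, 1 - p))
  psi * det_prob + (1 - psi) * as.numeric(all(y == 0))
}

# Vectorized pointwise log-likelihood over posterior draws.
# draws: list with beta0 (D), Beta (D x P or NULL), alpha (D x S or NULL),
# gamma0 (D), gamma_effort (D or NULL), delta (D x L or NULL).
# design: see build_design(). Returns an n x D matrix.
pointwise_loglik_draws <- function(draws, design) {
  n <- nrow(design$y); K <- ncol(design$y)
  D <- length(draws$beta0)
  eta_psi <- matrix(draws$beta0, n, D, byrow = TRUE)
  if (!is.null(draws$Beta) && ncol(design$Xpsi) > 0)
    eta_psi <- eta_psi + design$Xpsi %*% t(draws$Beta)
  if (!is.null(draws$alpha))
    eta_psi <- eta_psi + t(draws$alpha[, design$station_index, drop = FALSE])
  log_psi <- plogis(eta_psi, log.p = TRUE)
  log_1mpsi <- plogis(-eta_psi, log.p = TRUE)

  acc <- matrix(0, n, D)
  for (t in seq_len(K)) {
    obs <- !is.na(design$y[, t])
    if (!any(obs)) next
    eta_p <- matrix(draws$gamma0, sum(obs), D, byrow = TRUE)
    if (!is.null(draws$gamma_effort))
      eta_p <- eta_p + design$effz[obs, t] %o% draws$gamma_effort
    if (!is.null(draws$delta))
      eta_p <- eta_p + t(draws$delta[, design$survey_index[obs], drop = FALSE])
    yt <- design$y[obs, t]
    ll <- ifelse(yt == 1, 1, 0) * plogis(eta_p, log.p = TRUE) +
      ifelse(yt == 1, 0, 1) * plogis(-eta_p, log.p = TRUE)
    acc[obs, ] <- acc[obs, ] + ll
  }
  detected <- rowSums(design$y == 1L, na.rm = TRUE) > 0
  out <- log_psi + acc
  if (any(!detected)) {
    i0 <- which(!detected)
    out[i0, ] <- log_add(out[i0, , drop = FALSE], log_1mpsi[i0, , drop = FALSE])
  }
  if (any(!is.finite(out)))
    stop_("non-finite site log-likelihood (first offending site: %d)",
          which(!is.finite(rowSums(out)))[1])
  out
}

# single parameter set -> draws-of-one representation
params_to_draws <- function(params, design) {
  P <- ncol(design$Xpsi)
  terms <- colnames(design$Xpsi)
  Beta <- NULL
  if (P > 0) {
    if (!all(terms %in% names(params$beta)))
      stop_("params$beta must name all occupancy terms: %s",
            paste(terms, collapse = ", "))
    Beta <- matrix(params$beta[terms], 1, P)
  }
  alpha <- NULL
  if (!is.null(design$station_levels) && !is.null(params$alpha)) {
    if (!all(design$station_levels %in% names(params$alpha)))
      stop_("params$alpha must name every station")
    alpha <- matrix(params$alpha[design$station_levels], 1)
  }
  delta <- NULL
  if (!is.null(design$survey_levels)) {
    if (!all(design$survey_levels %in% names(params$survey_effects)))
      stop_("params$survey_effects must name every survey level")
    delta <- matrix(params$survey_effects[design$survey_levels], 1)
  }
  gamma_effort <- if (design$use_effort) params$gamma_effort else NULL
  if (design$use_effort && is.null(gamma_effort))
    stop_("params$gamma_effort required when effort is a detection term")
  list(beta0 = params$beta0, Beta = Beta, alpha = alpha,
       gamma0 = params$gamma0, gamma_effort = gamma_effort, delta = delta)
}

#' Occupancy log-likelihood for a fixed parameter set
#'
#' Evaluates the marginalized occupancy likelihood over all sites for one
#' set of parameters on the logit-linear predictors
#' `logit(psi_i) = beta0 + sum_j beta_j x_ij + alpha_station(i)` and
#' `logit(p_it) = gamma0 + gamma_effort * effz_it + delta_survey(i)`.
#'
#' @param params list with `beta0`, named `beta`, optional named `alpha`,
#'   `gamma0`, `gamma_effort`, named `survey_effects` (as the model spec
#'   requires).
#' @param history a [detection_history].
#' @param cov a `std_covariates` table aligned to the history by
#'   (station_id, year).
#' @param spec an [occu_spec()].
#' @return list with `total` (scalar log-likelihood) and `pointwise`
#'   (per-site vector), the quantities needed for LOO.
#' @export
occu_loglik <- function(params, history, cov, spec) {
  design <- build_design(history, cov, spec)
  ll <- pointwise_loglik_draws(params_to_draws(params, design), design)
  list(total = sum(ll[, 1]), pointwise = ll[, 1])
}
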