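# Leave-one-out model comparison via Pareto-smoothed importance sampling.
#
# elpd_i = log E_post[ p(y_i | theta) ] with the expectation under the
# leave-one-out posterior, approximated by importance sampling with ratios
# 1/p(y_i | theta) whose heavy right tail is stabilized by replacing the
# largest ratios with quantiles of a fitted generalized Pareto
# distribution (empirical-Bayes profile fit).

# Profile-posterior generalized Pareto fit to positive exceedances.
# Returns shape k (positive = heavy tail) and scale sigma; k is shrunk
# towards 0.5 with a weakly informative prior for small tail samples.
gpd_fit <- function(x) {
  x <- sort.int(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * xstar)
  kzs <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  ll <- n * (log(theta / kzs) + kzs - 1)
  w <- exp(ll - logsumexp(ll))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))      # = -k_profile; heavy tail => k > 0
  sigma <- -k / theta_hat
  k <- k * n / (n + 10) + 0.5 * 10 / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd_ <- function(p, k, sigma) {
  if (abs(k) < 1e-7) return(-sigma * log1p(-p))
  sigma * ((1 - p)^(-k) - 1) / k
}

# Smooth one vector of log importance ratios; returns normalized log
# weights and the Pareto-k diagnostic.
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(S / 5, 3 * sqrt(S)))
  k <- NA_real_
  if (S >= 25 && M >= 5) {
    ord <- order(lr)
    tail_ids <- ord[(S - M + 1):S]
    cutoff <- lr[ord[S - M]]
    r <- exp(lr)
    exc <- r[tail_ids] - exp(cutoff)
    if (max(exc) > sqrt(.Machine$double.eps)) {
      fit <- gpd_fit(exc[exc > 0] + 1e-15)
      k <- fit$k
      q <- exp(cutoff) + qgpd_((seq_len(M) - 0.5) / M, fit$k, fit$sigma)
      r[tail_ids] <- pmin(q, max(r))
      lr <- log(r)
    }
  }
  list(log_weights = lr - logsumexp(lr), k = k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Computes the leave-one-out expected log pointwise predictive density
#' (elpd) from a fit's per-site, per-draw log-likelihood matrix using
#' Pareto-smoothed importance sampling, with the Pareto shape diagnostic
#' per site.
#'
#' @param fit an `occu_fit` (or a sites x draws log-likelihood matrix).
#' @return object of class `occu_loo`: list with `elpd`, `se` (
#'   `sd(elpd_i) * sqrt(n)`), `pointwise` (data frame with `elpd_i` and
#'   `pareto_k`), `n`.
#' @export
loo_elpd <- function(fit) {
  ll <- if (inherits(fit, "occu_fit")) fit$pointwise_loglik else as.matrix(fit)
  n <- nrow(ll)
  if (n < 1L) stop_("empty log-likelihood matrix")
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[i, ])
    elpd_i[i] <- logsumexp(sm$log_weights + ll[i, ])
    k_i[i] <- sm$k
  }
  bad <- which(k_i > 0.7)
  if (length(bad))
    warning(sprintf("unreliable importance ratios (Pareto k > 0.7) for %d site(s): %s",
                    length(bad), paste(head(bad, 10), collapse = ", ")),
            call. = FALSE)
  structure(list(elpd = sum(elpd_i), se = sd(elpd_i) * sqrt(n),
                 pointwise = data.frame(elpd_i = elpd_i, pareto_k = k_i),
                 n = n),
            class = "occu_loo")
}

#' @export
print.occu_loo <- function(x, ...) {
  cat(sprintf("<occu_loo> elpd %.2f (se %.2f), n = %d, max Pareto-k %.2f\n",
              x$elpd, x$se, x$n, max(x$pointwise$pareto_k, na.rm = TRUE)))
  invisible(x)
}

# Bayesian-bootstrap pseudo-BMA weights from an n x K pointwise elpd matrix
pseudo_bma_weights <- function(elpd_mat, n_boot = 1000, seed = 1) {
  n <- nrow(elpd_mat); K <- ncol(elpd_mat)
  if (K == 1L) return(1)
  with_seed_(seed, {
    acc <- numeric(K)
    for (b in seq_len(n_boot)) {
      g <- rgamma(n, 1)
      w <- g / sum(g)
      z <- n * drop(crossprod(w, elpd_mat))
      acc <- acc + exp(z - logsumexp(z))
    }
    acc / n_boot
  })
}

# stacking of predictive distributions on the simplex
stacking_weights <- function(elpd_mat) {
  K <- ncol(elpd_mat)
  if (K == 1L) return(1)
  obj <- function(u) {
    lw <- c(0, u)
    lw <- lw - logsumexp(lw)
    -sum(apply(elpd_mat + matrix(lw, nrow(elpd_mat), K, byrow = TRUE),
               1, logsumexp))
  }
  fit <- optim(rep(0, K - 1), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  w <- exp(c(0, fit$par))
  w / sum(w)
}

#' Compare fitted occupancy models by LOO elpd
#'
#' Ranks models by PSIS-LOO elpd and attaches model weights computed from
#' the pointwise elpd contributions, by Bayesian-bootstrap pseudo-BMA
#' (default; regularizes by the pointwise variance) or by stacking of
#' predictive distributions.
#'
#' @param fits named list of `occu_fit` objects sharing the same site set.
#' @param method `"pseudo-bma"` or `"stacking"`.
#' @param n_boot bootstrap replicates for pseudo-BMA.
#' @param seed RNG seed for the Bayesian bootstrap.
#' @return object of class `model_comparison`: data frame with columns
#'   `model`, `elpd`, `se`, `delta_elpd`, `weight`, sorted by elpd; the best
#'   model's label in `attr(, "best")`.
#' @export
compare_models <- function(fits, method = c("pseudo-bma", "stacking"),
                           n_boot = 1000, seed = 1) {
  method <- match.arg(method)
  if (inherits(fits, "occu_fit")) fits <- list(fits)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- vapply(fits, function(f) f$spec$label, character(1))
  keys <- lapply(fits, function(f)
    paste(f$design$site$station_id, f$design$site$year))
  if (!all(vapply(keys, identical, logical(1), y = keys[[1]])))
    stop_("models were fitted to different site sets and cannot be compared")
  loos <- lapply(fits, loo_elpd)
  elpd_mat <- vapply(loos, function(l) l$pointwise$elpd_i,
                     numeric(loos[[1]]$n))
  elpd_mat <- matrix(elpd_mat, ncol = length(fits),
                     dimnames = list(NULL, names(fits)))
  w <- switch(method,
              "pseudo-bma" = pseudo_bma_weights(elpd_mat, n_boot, seed),
              "stacking" = stacking_weights(elpd_mat))
  tab <- data.frame(
    model = names(fits),
    elpd = vapply(loos, `[[`, numeric(1), "elpd"),
    se = vapply(loos, `[[`, numeric(1), "se"),
    weight = as.numeric(w),
    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$elpd), ]
  tab$delta_elpd <- tab$elpd - tab$elpd[1]
  tab <- tab[, c("model", "elpd", "se", "delta_elpd", "weight")]
  rownames(tab) <- NULL
  structure(tab, best = tab$model[1], method = method,
            class = c("model_comparison", "data.frame"))
}

#' Backward elimination of occupancy terms
#'
#' Starting from a fitted specification, repeatedly removes the occupancy
#' term with the smallest standardized effect size (|posterior mean| / sd),
#' refits, and accepts the reduced model when its LOO elpd does not drop by
#' more than `margin`; stops at the first rejected removal or when no terms
#' remain.
#'
#' @param start_spec an [occu_spec()].
#' @param history,cov data as in [fit_occupancy()].
#' @param margin allowed elpd decrease per removal (default 0).
#' @param fit_args list of arguments forwarded to [fit_occupancy()]
#'   (chains, iterations, seed, ...).
#' @return list with `spec` (the selected specification) and `trail` (data
#'   frame recording every candidate's elpd and acceptance).
#' @export
backward_eliminate <- function(start_spec, history, cov, margin = 0,
                               fit_args = list(n_chains = 2, n_iter = 2000,
                                               n_adapt = 300, seed = 1)) {
  trail <- data.frame(step = integer(), model = character(),
                      removed_term = character(), elpd = numeric(),
                      se = numeric(), accepted = logical(),
                      stringsAsFactors = FALSE)
  if (!length(start_spec$psi_terms))
    return(list(spec = start_spec, trail = trail))
  fit1 <- function(sp) do.call(fit_occupancy,
                               c(list(sp, history, cov), fit_args))
  cur_spec <- start_spec
  cur_fit <- fit1(cur_spec)
  cur_loo <- loo_elpd(cur_fit)
  trail <- rbind(trail, data.frame(step = 0L, model = cur_spec$label,
                                   removed_term = NA_character_,
                                   elpd = cur_loo$elpd, se = cur_loo$se,
                                   accepted = TRUE))
  step <- 0L
  while (length(cur_spec$psi_terms)) {
    step <- step + 1L
    summ <- summarize_posterior(cur_fit)
    bn <- sprintf("beta[%s]", cur_spec$psi_terms)
    es <- abs(summ$mean[match(bn, summ$parameter)]) /
      summ$sd[match(bn, summ$parameter)]
    weakest <- cur_spec$psi_terms[which.min(es)]
    cand_spec <- occu_spec(setdiff(cur_spec$psi_terms, weakest),
                           cur_spec$p_terms,
                           cur_spec$random_station_intercept,
                           cur_spec$priors)
    cand_fit <- fit1(cand_spec)
    cand_loo <- loo_elpd(cand_fit)
    accepted <- cand_loo$elpd >= cur_loo$elpd - margin
    trail <- rbind(trail, data.frame(step = step, model = cand_spec$label,
                                     removed_term = weakest,
                                     elpd = cand_loo$elpd, se = cand_loo$se,
                                     accepted = accepted))
    if (!accepted) break
    cur_spec <- cand_spec; cur_fit <- cand_fit; cur_loo <- cand_loo
  }
  list(spec = cur_spec, trail = trail)
}

#' The candidate model set of the habitat-use analysis
#'
#' Builds the named hypotheses of the analysis: a null model; a null model
#' with year on occupancy; the most-parameterized (global) model with and
#' without the random station intercept; an environmental-covariates model
#' (tree cover, distance to water, elevation, ruggedness); and an
#' anthropogenic-covariates model (distance to settlements and roads). All
#' models except the pure null carry effort on detection; the global models
#' also carry the survey factor.
#'
#' @param priors an [occu_priors()] shared by all specs.
#' @return named list of [occu_spec()] objects.
#' @export
candidate_model_set <- function(priors = occu_priors()) {
  env <- c("tree_cover", "dist_water", "elevation", "ruggedness")
  anthro <- c("dist_settlement", "dist_road")
  list(
    null = occu_spec(priors = priors, label = "P(.)psi(.)"),
    year = occu_spec("year", "effort", TRUE, priors,
                     label = "P(effort)psi(year)"),
    global_re = occu_spec(c(env, anthro), c("effort", "survey"), TRUE, priors,
                          label = "P(effort+survey)psi(global)+station"),
    global_fixed = occu_spec(c(env, anthro), c("effort", "survey"), FALSE,
                             priors,
                             label = "P(effort+survey)psi(global)"),
    environmental = occu_spec(env, "effort", TRUE, priors,
                              label = "P(effort)psi(tc+water+elev+tri)"),
    anthropogenic = occu_spec(anthro, "effort", TRUE, priors,
                              label = "P(effort)psi(set+road)")
  )
}
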