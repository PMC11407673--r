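# MacKenzie-Bailey chi-square goodness of fit with posterior-predictive
# simulation.
#
# Sites are cohorted by their occasion missingness pattern; within each
# cohort every possible detection history h is enumerated, its expected
# frequency E_h = sum_i Pr(history = h | params, site i) computed from the
# occupancy model, and X2 = sum (O_h - E_h)^2 / E_h accumulated over
# cohorts, pooling rare expected cells into a residual cell.

# Precompute cohort structure from the y matrix: per missingness pattern,
# site indices, active columns, all possible histories, and the observed
# history index per site. Row 1 of H is always the all-zero history.
mb_cohorts_ <- function(y) {
  pat <- apply(is.na(y), 1, paste, collapse = "")
  lapply(split(seq_len(nrow(y)), pat), function(sites) {
    active <- which(!is.na(y[sites[1], ]))
    Kc <- length(active)
    H <- as.matrix(expand.grid(rep(list(0:1), Kc)))[, Kc:1, drop = FALSE]
    dimnames(H) <- NULL
    pow <- 2^((Kc - 1):0)
    obs_idx <- as.integer(y[sites, active, drop = FALSE] %*% pow) + 1L
    list(sites = sites, active = active, Kc = Kc, H = H, pow = pow,
         obs_idx = obs_idx,
         labels = apply(H, 1, paste, collapse = ""))
  })
}

# Expected history frequencies for one cohort under fixed psi/p
mb_expected_ <- function(cohort, psi, p) {
  sites <- cohort$sites
  pc <- p[sites, cohort$active, drop = FALSE]
  pc <- pmin(pmax(pc, 1e-12), 1 - 1e-12)
  lp <- t(log(pc)); l1p <- t(log1p(-pc))          # Kc x nc
  cond <- exp(cohort$H %*% lp + (1 - cohort$H) %*% l1p)  # nh x nc
  psic <- psi[sites]
  pr <- cond * matrix(psic, nrow(cond), length(sites), byrow = TRUE)
  pr[1, ] <- pr[1, ] + (1 - psic)                 # all-zero history
  rowSums(pr)
}

# chi-square over one cohort's cells with pooling of small expected counts
chisq_cells_ <- function(O, E, pool_floor) {
  small <- E < pool_floor
  if (sum(small) > 1L) {
    Ep <- c(E[!small], sum(E[small]))
    Op <- c(O[!small], sum(O[small]))
    pooled <- c(rep(FALSE, sum(!small)), TRUE)
    labels_keep <- which(!small)
  } else {
    Ep <- E; Op <- O; pooled <- rep(FALSE, length(E))
    labels_keep <- seq_along(E)
  }
  contrib <- ifelse(Ep > 0, (Op - Ep)^2 / Ep, ifelse(Op > 0, Inf, 0))
  list(stat = sum(contrib), E = Ep, O = Op, pooled = pooled,
       labels_keep = labels_keep)
}

obs_counts_ <- function(cohorts, idx_list = NULL) {
  lapply(seq_along(cohorts), function(ci) {
    co <- cohorts[[ci]]
    idx <- if (is.null(idx_list)) co$obs_idx else idx_list[[ci]]
    tabulate(idx, nbins = nrow(co$H))
  })
}

stat_from_E_ <- function(E_list, O, pool_floor) {
  s <- 0
  for (ci in seq_along(E_list))
    s <- s + chisq_cells_(O[[ci]], E_list[[ci]], pool_floor)$stat
  s
}

# psi vector and p matrix (NA at unsurveyed cells) for one retained draw
draw_psi_p_ <- function(dr, design, psi_all, d) {
  n <- nrow(design$y); K <- ncol(design$y)
  eta_p <- matrix(dr$gamma0[d], n, K)
  if (!is.null(dr$gamma_effort))
    eta_p <- eta_p + dr$gamma_effort[d] * design$effz
  if (!is.null(dr$delta))
    eta_p <- eta_p + matrix(dr$delta[d, design$survey_index], n, K)
  p <- plogis(eta_p)
  p[is.na(design$y)] <- NA_real_
  list(psi = psi_all[, d], p = p)
}

#' MacKenzie-Bailey chi-square statistic for fixed parameters
#'
#' Computes the observed-versus-expected chi-square over all enumerable
#' detection histories for one parameter set, cohorting sites by their
#' missingness pattern and pooling expected cells below `pool_floor` into a
#' residual cell per cohort. A residual cell with zero expectation but
#' positive observation yields an infinite statistic (the model declares an
#' observed history impossible).
#'
#' @param params parameter list as in [occu_loglik()].
#' @param history a [detection_history].
#' @param cov standardized covariates.
#' @param spec an [occu_spec()].
#' @param pool_floor minimum expected count of an unpooled cell; the
#'   default 0 pools nothing, the canonical form of the test (pooling cells
#'   that were never observed does not change the statistic, and the
#'   simulation-based p-value does not rely on a chi-square approximation).
#' @return list with `stat` (X2 >= 0) and `cohort_table` (data frame of
#'   cohort pattern, history label, observed and expected frequency,
#'   pooled flag).
#' @export
mb_chisq <- function(params, history, cov, spec, pool_floor = 0) {
  design <- build_design(history, cov, spec)
  dr1 <- params_to_draws(params, design)
  # promote the single parameter set to the draw helpers' layout
  dr <- list(beta0 = dr1$beta0, Beta = dr1$Beta, alpha = dr1$alpha,
             gamma0 = dr1$gamma0, gamma_effort = dr1$gamma_effort,
             delta = dr1$delta)
  n <- nrow(design$y)
  eta_psi <- rep(dr$beta0, n)
  if (!is.null(dr$Beta) && ncol(design$Xpsi) > 0)
    eta_psi <- eta_psi + drop(design$Xpsi %*% t(dr$Beta))
  if (!is.null(dr$alpha)) eta_psi <- eta_psi + dr$alpha[1, design$station_index]
  psi_all <- matrix(plogis(eta_psi), n, 1)
  pp <- draw_psi_p_(dr, design, psi_all, 1L)

  cohorts <- mb_cohorts_(design$y)
  O <- obs_counts_(cohorts)
  stat <- 0
  rows <- list()
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    E <- mb_expected_(co, pp$psi, pp$p)
    cells <- chisq_cells_(O[[ci]], E, pool_floor)
    stat <- stat + cells$stat
    lab <- c(co$labels[cells$labels_keep], if (any(cells$pooled)) "other")
    rows[[ci]] <- data.frame(
      cohort = paste(ifelse(is.na(design$y[co$sites[1], ]), ".", "o"),
                     collapse = ""),
      history = lab, observed = cells$O, expected = cells$E,
      pooled = cells$pooled, stringsAsFactors = FALSE)
  }
  list(stat = stat, cohort_table = do.call(rbind, rows))
}

#' Posterior-predictive MacKenzie-Bailey goodness-of-fit test
#'
#' For each of `n_sim` posterior draws, computes the observed-data
#' chi-square at that draw, simulates a replicate dataset from the model at
#' the same draw (identical design and missingness pattern), and computes
#' the replicate's chi-square. The Bayesian p-value is the fraction of
#' draws whose replicate statistic is at least the observed one; values
#' near 0 indicate lack of fit.
#'
#' @param fit an `occu_fit` (conventionally of the global model).
#' @param n_sim number of posterior draws used (>= 100 recommended).
#' @param pool_floor pooling floor for expected cells.
#' @param seed RNG seed for the replicate simulations.
#' @return object of class `gof_result`: list with `observed_stat`
#'   (posterior mean of the per-draw observed-data statistics), `obs_stats`,
#'   `sim_stats`, `p_value`, `n_sim`, `cohort_table` (observed counts vs
#'   posterior-mean expected counts).
#' @export
mb_gof <- function(fit, n_sim = 1000, pool_floor = 0, seed = 1) {
  if (n_sim < 100)
    warning("n_sim < 100 gives an unstable p-value", call. = FALSE)
  design <- fit$design
  y <- design$y
  n <- nrow(y)
  D <- nrow(fit$draws)
  take <- unique(round(seq(1, D, length.out = min(n_sim, D))))
  dr <- extract_draws(fit)
  psi_all <- psi_draws_(fit)
  cohorts <- mb_cohorts_(y)
  O <- obs_counts_(cohorts)
  obs_mask <- !is.na(y)
  Emean <- lapply(cohorts, function(co) rep(0, nrow(co$H)))

  obs_stats <- numeric(length(take))
  sim_stats <- numeric(length(take))
  with_seed_(seed, {
    for (s in seq_along(take)) {
      pp <- draw_psi_p_(dr, design, psi_all, take[s])
      E_list <- lapply(cohorts, mb_expected_, psi = pp$psi, p = pp$p)
      for (ci in seq_along(cohorts))
        Emean[[ci]] <- Emean[[ci]] + E_list[[ci]]
      obs_stats[s] <- stat_from_E_(E_list, O, pool_floor)

      z_rep <- rbinom(n, 1L, pp$psi)
      y_rep <- matrix(NA_integer_, n, ncol(y))
      y_rep[obs_mask] <- rbinom(sum(obs_mask), 1L,
                                z_rep[row(y)[obs_mask]] * pp$p[obs_mask])
      idx_rep <- lapply(cohorts, function(co)
        as.integer(y_rep[co$sites, co$active, drop = FALSE] %*% co$pow) + 1L)
      sim_stats[s] <- stat_from_E_(E_list, obs_counts_(cohorts, idx_rep),
                                   pool_floor)
    }
  })

  cohort_table <- do.call(rbind, lapply(seq_along(cohorts), function(ci) {
    co <- cohorts[[ci]]
    data.frame(cohort = paste(ifelse(is.na(y[co$sites[1], ]), ".", "o"),
                              collapse = ""),
               history = co$labels, observed = O[[ci]],
               expected = Emean[[ci]] / length(take),
               stringsAsFactors = FALSE)
  }))

  structure(list(observed_stat = mean(obs_stats),
                 obs_stats = obs_stats, sim_stats = sim_stats,
                 p_value = mean(sim_stats >= obs_stats),
                 n_sim = length(take), cohort_table = cohort_table),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> X2 = %.2f (posterior mean), P = %.3f (%d draws)\n",
              x$observed_stat, x$p_value, x$n_sim))
  invisible(x)
}
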