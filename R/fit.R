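# Model specification and Bayesian fitting (JAGS backend).

#' Prior specification for the occupancy model
#'
#' Weakly-informative defaults suitable for z-scored predictors: slopes
#' normal(0, 2.5); intercepts logistic(0, 1), which is uniform on the
#' probability scale after the inverse-logit link and is the conventional
#' non-informative intercept prior for occupancy models (a wide normal on
#' the logit scale is bathtub-shaped on the probability scale and, under
#' the weakly-identified psi/p trade-off of sparse detections, actively
#' pulls the posterior towards degenerate occupancy); random-intercept SD
#' exponential with mean 1, the conventional random-effect-SD default of
#' Bayesian occupancy backends, whose decaying tail keeps the
#' variance-inflation ridge of sparse data in check. Supported
#' distributions: `"normal"`, `"cauchy"`, `"logistic"` for
#' slopes/intercepts and `"half-normal"`, `"half-cauchy"`,
#' `"half-logistic"`, `"exponential"` (scale = mean) for the SD.
#'
#' @param slope_dist,slope_scale prior on occupancy/detection slopes.
#' @param intercept_dist,intercept_scale prior on intercepts.
#' @param sigma_dist,sigma_scale positive-support prior on the random
#'   station-intercept SD.
#' @return an object of class `occu_priors`.
#' @export
occu_priors <- function(slope_dist = "normal", slope_scale = 2.5,
                        intercept_dist = "logistic", intercept_scale = 1,
                        sigma_dist = "exponential", sigma_scale = 1) {
  assert_number(slope_scale, "slope_scale", lower = 1e-12)
  assert_number(intercept_scale, "intercept_scale", lower = 1e-12)
  assert_number(sigma_scale, "sigma_scale", lower = 1e-12)
  ok <- c("normal", "cauchy", "logistic")
  if (!slope_dist %in% ok || !intercept_dist %in% ok)
    stop_("slope/intercept priors must be one of: %s", paste(ok, collapse = ", "))
  sig_ok <- c(paste0("half-", ok), "exponential")
  if (!sigma_dist %in% sig_ok)
    stop_("sigma prior must be one of: %s", paste(sig_ok, collapse = ", "))
  structure(list(slope_dist = slope_dist, slope_scale = slope_scale,
                 intercept_dist = intercept_dist,
                 intercept_scale = intercept_scale,
                 sigma_dist = sigma_dist, sigma_scale = sigma_scale),
            class = "occu_priors")
}

prior_jags_ <- function(dist, scale) {
  switch(dist,
    "normal" = sprintf("dnorm(0, %.10g)", 1 / scale^2),
    "cauchy" = sprintf("dt(0, %.10g, 1)", 1 / scale^2),
    "logistic" = sprintf("dlogis(0, %.10g)", 1 / scale),
    "half-normal" = sprintf("dnorm(0, %.10g) T(0,)", 1 / scale^2),
    "half-cauchy" = sprintf("dt(0, %.10g, 1) T(0,)", 1 / scale^2),
    "half-logistic" = sprintf("dlogis(0, %.10g) T(0,)", 1 / scale),
    "exponential" = sprintf("dexp(%.10g)", 1 / scale),
    stop_("unsupported prior distribution '%s'", dist))
}

#' Occupancy model specification
#'
#' Names the occupancy-side covariates, the detection-side observation
#' covariates, and whether a random station intercept absorbs the
#' pseudoreplication of the stacked camera-year design.
#'
#' @param psi_terms character vector of site covariates on occupancy
#'   (columns of the standardized covariate table; `"year"` is allowed and
#'   is z-scored internally). Empty for a null model.
#' @param p_terms subset of `c("effort", "survey")`.
#' @param random_station_intercept logical.
#' @param priors an [occu_priors()].
#' @param label optional model label used in comparison tables.
#' @return an object of class `occu_spec`.
#' @export
occu_spec <- function(psi_terms = character(), p_terms = character(),
                      random_station_intercept = FALSE,
                      priors = occu_priors(), label = NULL) {
  bad <- setdiff(p_terms, c("effort", "survey"))
  if (length(bad))
    stop_("unknown detection terms: %s", paste(bad, collapse = ", "))
  if (!inherits(priors, "occu_priors"))
    stop_("'priors' must come from occu_priors()")
  if (is.null(label))
    label <- sprintf("P(%s)psi(%s)%s",
                     if (length(p_terms)) paste(p_terms, collapse = "+") else ".",
                     if (length(psi_terms)) paste(psi_terms, collapse = "+") else ".",
                     if (random_station_intercept) "+station" else "")
  structure(list(psi_terms = unname(psi_terms), p_terms = unname(p_terms),
                 random_station_intercept = isTRUE(random_station_intercept),
                 priors = priors, label = label),
            class = "occu_spec")
}

#' @export
print.occu_spec <- function(x, ...) {
  cat(sprintf("<occu_spec> %s\n", x$label))
  invisible(x)
}

# Align covariates with the history and assemble all model inputs.
build_design <- function(history, cov, spec) {
  if (!inherits(history, "detection_history"))
    stop_("'history' must be a detection_history")
  if (!inherits(spec, "occu_spec")) stop_("'spec' must be an occu_spec")
  site <- history$site
  key_h <- paste(site$station_id, site$year)
  key_c <- paste(cov$station_id, cov$year)
  if (anyDuplicated(key_c)) stop_("duplicated (station_id, year) in covariates")
  idx <- match(key_h, key_c)
  if (anyNA(idx))
    stop_("covariates missing for sites: %s",
          paste(head(key_h[is.na(idx)], 5), collapse = "; "))
  covr <- cov[idx, , drop = FALSE]

  tp <- transform_params(cov) %||% list()
  Xpsi <- matrix(0, nrow(site), 0)
  year_params <- NULL
  if ("year" %in% spec$psi_terms) {
    if (sd(covr$year) == 0) stop_("'year' has zero variance across sites")
    year_params <- c(mean = mean(covr$year), sd = sd(covr$year))
  }
  if (length(spec$psi_terms)) {
    cols <- lapply(spec$psi_terms, function(v) {
      if (v == "year") {
        (covr$year - year_params["mean"]) / year_params["sd"]
      } else {
        if (!v %in% names(covr)) stop_("occupancy term '%s' not found", v)
        if (!v %in% names(tp))
          stop_("occupancy term '%s' is not standardized; run z_transform()", v)
        covr[[v]]
      }
    })
    Xpsi <- do.call(cbind, cols)
    colnames(Xpsi) <- spec$psi_terms
  }

  station_levels <- NULL; station_index <- NULL
  if (spec$random_station_intercept) {
    station_levels <- unique(site$station_id)
    station_index <- match(site$station_id, station_levels)
  }
  survey_levels <- NULL; survey_index <- NULL
  if ("survey" %in% spec$p_terms) {
    if (!"survey" %in% names(site))
      stop_("history has no 'survey' column but the model includes survey")
    lv <- unique(site$survey)
    survey_levels <- if ("OC" %in% lv) c("OC", sort(setdiff(lv, "OC")))
                     else sort(lv)
    survey_index <- match(site$survey, survey_levels)
  }
  use_effort <- "effort" %in% spec$p_terms
  effz <- history$effort * 0
  effort_params <- c(mean = 0, sd = 1)
  if (use_effort) {
    active <- history$effort > 0
    m <- mean(history$effort[active]); s <- sd(history$effort[active])
    if (!is.finite(s) || s == 0) s <- 1
    effz <- (history$effort - m) / s
    effort_params <- c(mean = m, sd = s)
  }
  list(y = history$y, Xpsi = Xpsi,
       station_levels = station_levels, station_index = station_index,
       survey_levels = survey_levels, survey_index = survey_index,
       use_effort = use_effort, effz = effz, effort_params = effort_params,
       year_params = year_params, site = site)
}

jags_model_string <- function(spec, P, S, L) {
  pr <- spec$priors
  ip <- prior_jags_(pr$intercept_dist, pr$intercept_scale)
  sp <- prior_jags_(pr$slope_dist, pr$slope_scale)
  lines <- c("model {", sprintf("  beta0 ~ %s", ip),
             sprintf("  gamma0 ~ %s", ip))
  if (P > 0) lines <- c(lines, sprintf("  for (j in 1:%d) { beta[j] ~ %s }", P, sp))
  if (spec$random_station_intercept)
    lines <- c(lines,
               sprintf("  sigma ~ %s", prior_jags_(pr$sigma_dist, pr$sigma_scale)),
               "  tau_a <- pow(sigma, -2)",
               sprintf("  for (s in 1:%d) { alpha[s] ~ dnorm(0, tau_a) }", S))
  if ("effort" %in% spec$p_terms)
    lines <- c(lines, sprintf("  gamma_e ~ %s", sp))
  if ("survey" %in% spec$p_terms)
    lines <- c(lines, "  delta[1] <- 0",
               sprintf("  for (l in 2:%d) { delta[l] ~ %s }", L, sp))
  psi_lp <- "beta0"
  if (P > 0) psi_lp <- paste0(psi_lp, " + inprod(X[i,], beta)")
  if (spec$random_station_intercept)
    psi_lp <- paste0(psi_lp, " + alpha[station[i]]")
  p_lp <- "gamma0"
  if ("effort" %in% spec$p_terms) p_lp <- paste0(p_lp, " + gamma_e*effz[m]")
  if ("survey" %in% spec$p_terms) p_lp <- paste0(p_lp, " + delta[survey[m]]")
  lines <- c(lines,
    "  for (i in 1:n) {",
    sprintf("    logit(psi[i]) <- %s", psi_lp),
    "    z[i] ~ dbern(psi[i])",
    "  }",
    "  for (m in 1:M) {",
    sprintf("    logit(p[m]) <- %s", p_lp),
    "    y[m] ~ dbern(z[site[m]] * p[m])",
    "  }",
    "}")
  paste(lines, collapse = "\n")
}

#' Fit a Bayesian single-season occupancy model
#'
#' Samples the posterior of the occupancy model by MCMC (JAGS backend; the
#' discrete latent habitat-use state is sampled directly). Per-occasion
#' effort is z-scored with its own mean/SD before entering the detection
#' predictor; the survey factor uses OC as the reference level when present.
#' Defaults follow the study convention of four chains of 40,000 iterations
#' with half discarded as burn-in; reduce these for exploratory fits.
#'
#' @param spec an [occu_spec()].
#' @param history a [detection_history].
#' @param cov standardized covariates from [z_transform()].
#' @param n_chains number of chains (>= 2 for convergence checks).
#' @param n_iter iterations per chain, including burn-in.
#' @param burn_fraction fraction of `n_iter` discarded.
#' @param n_adapt adaptation iterations for the sampler.
#' @param seed integer seed; chain c uses seed + c - 1.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `occu_fit` with elements `draws` (matrix,
#'   retained draws x parameters), `chain` (chain id per draw), `rhat`
#'   (split-Rhat per parameter), `pointwise_loglik` (sites x draws matrix of
#'   log-likelihood contributions, for LOO and GOF), `spec`, `design`,
#'   `seed` and the sampling dimensions.
#' @export
fit_occupancy <- function(spec, history, cov,
                          n_chains = 4, n_iter = 40000, burn_fraction = 0.5,
                          n_adapt = 1000, seed = 1, quiet = TRUE) {
  assert_number(n_chains, "n_chains", lower = 1)
  assert_number(n_iter, "n_iter", lower = 4)
  assert_number(burn_fraction, "burn_fraction", lower = 0, upper = 0.95)
  assert_number(seed, "seed", lower = -2^31 + 10, upper = 2^31 - 10 - n_chains)
  design <- build_design(history, cov, spec)
  y <- design$y
  n <- nrow(y)
  detected <- rowSums(y == 1L, na.rm = TRUE) > 0
  if (all(detected) || !any(detected))
    warning("data contain only detected or only undetected sites; ",
            "the occupancy intercept is weakly identified", call. = FALSE)

  obs <- which(!is.na(y), arr.ind = TRUE)
  dat <- list(n = n, M = nrow(obs), site = obs[, 1],
              y = y[obs])
  P <- ncol(design$Xpsi)
  if (P > 0) dat$X <- design$Xpsi
  if (design$use_effort) dat$effz <- design$effz[obs]
  if (!is.null(design$survey_levels)) dat$survey <- design$survey_index[obs[, 1]]
  if (spec$random_station_intercept) dat$station <- design$station_index
  S <- length(design$station_levels)
  L <- length(design$survey_levels)

  model_str <- jags_model_string(spec, P, S, L)
  monitors <- c("beta0", "gamma0")
  if (P > 0) monitors <- c(monitors, "beta")
  if (design$use_effort) monitors <- c(monitors, "gamma_e")
  if (L > 0) monitors <- c(monitors, "delta")
  if (spec$random_station_intercept) monitors <- c(monitors, "sigma", "alpha")

  inits <- lapply(seq_len(n_chains), function(c) {
    ini <- list(z = rep(1L, n), beta0 = 0, gamma0 = 0,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed + c - 1))
    if (P > 0) ini$beta <- rep(0, P)
    if (design$use_effort) ini$gamma_e <- 0
    if (spec$random_station_intercept) ini$sigma <- 0.5
    ini
  })
  burn <- floor(n_iter * burn_fraction)
  sm <- tryCatch({
    jm <- rjags::jags.model(textConnection(model_str), data = dat,
                            inits = inits, n.chains = n_chains,
                            n.adapt = n_adapt, quiet = quiet)
    if (burn > 0) stats::update(jm, burn, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = n_iter - burn,
                        progress.bar = "none")
  }, error = function(e)
    stop_("MCMC sampling failed: %s", conditionMessage(e)))

  # rename JAGS indices to domain names
  rename <- function(nm) {
    nm <- sub("^sigma$", "sigma_station", nm)
    nm <- sub("^gamma_e$", "gamma[effort]", nm)
    # coda drops the index on length-1 monitored vectors
    if (P == 1L) nm[nm == "beta"] <- "beta[1]"
    if (L == 1L) nm[nm == "delta"] <- "delta[1]"
    if (S == 1L) nm[nm == "alpha"] <- "alpha[1]"
    for (j in seq_len(P))
      nm[nm == sprintf("beta[%d]", j)] <- sprintf("beta[%s]", spec$psi_terms[j])
    for (l in seq_len(L))
      nm[nm == sprintf("delta[%d]", l)] <-
        sprintf("delta[%s]", design$survey_levels[l])
    for (s in seq_len(S))
      nm[nm == sprintf("alpha[%d]", s)] <-
        sprintf("alpha[%s]", design$station_levels[s])
    nm
  }
  mats <- lapply(sm, as.matrix)
  draws <- do.call(rbind, mats)
  colnames(draws) <- rename(colnames(draws))
  chain <- rep(seq_len(n_chains), each = nrow(mats[[1]]))

  rhat <- vapply(colnames(draws), function(p) {
    split_rhat(matrix(draws[, p], ncol = n_chains))
  }, numeric(1))

  fit <- structure(list(draws = draws, chain = chain, n_chains = n_chains,
                        n_iter = n_iter, burn_fraction = burn_fraction,
                        rhat = rhat, spec = spec, design = design,
                        seed = as.integer(seed)),
                   class = "occu_fit")
  fit$pointwise_loglik <- pointwise_loglik_draws(extract_draws(fit), design)
  fit
}

# draws matrix -> structured draw list for the likelihood helpers
extract_draws <- function(fit) {
  d <- fit$draws
  spec <- fit$spec; design <- fit$design
  P <- ncol(design$Xpsi)
  Beta <- if (P > 0)
    d[, sprintf("beta[%s]", spec$psi_terms), drop = FALSE] else NULL
  alpha <- if (spec$random_station_intercept)
    d[, sprintf("alpha[%s]", design$station_levels), drop = FALSE] else NULL
  delta <- if (!is.null(design$survey_levels))
    d[, sprintf("delta[%s]", design$survey_levels), drop = FALSE] else NULL
  list(beta0 = d[, "beta0"], Beta = Beta, alpha = alpha,
       gamma0 = d[, "gamma0"],
       gamma_effort = if (design$use_effort) d[, "gamma[effort]"] else NULL,
       delta = delta,
       sigma = if (spec$random_station_intercept) d[, "sigma_station"] else NULL)
}

# per-draw psi at the training sites (n x D); alpha included when present
psi_draws_ <- function(fit) {
  dr <- extract_draws(fit)
  design <- fit$design
  n <- nrow(design$y); D <- length(dr$beta0)
  eta <- matrix(dr$beta0, n, D, byrow = TRUE)
  if (!is.null(dr$Beta) && ncol(design$Xpsi) > 0)
    eta <- eta + design$Xpsi %*% t(dr$Beta)
  if (!is.null(dr$alpha))
    eta <- eta + t(dr$alpha[, design$station_index, drop = FALSE])
  plogis(eta)
}

# per-draw p at observed site-occasions; returns D-vector of means and the
# full list when full = TRUE
p_draws_mean_ <- function(fit) {
  dr <- extract_draws(fit)
  design <- fit$design
  obs <- which(!is.na(design$y), arr.ind = TRUE)
  M <- nrow(obs); D <- length(dr$gamma0)
  eta <- matrix(dr$gamma0, M, D, byrow = TRUE)
  if (!is.null(dr$gamma_effort))
    eta <- eta + design$effz[obs] %o% dr$gamma_effort
  if (!is.null(dr$delta))
    eta <- eta + t(dr$delta[, design$survey_index[obs[, 1]], drop = FALSE])
  colMeans(plogis(eta))
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf("<occu_fit> %s\n  %d sites, %d chains x %d iter (%.0f%% burn-in), %d draws\n",
              x$spec$label, nrow(x$design$y), x$n_chains, x$n_iter,
              100 * x$burn_fraction, nrow(x$draws)))
  cat(sprintf("  max split-Rhat (non-random-effect): %.3f\n",
              max(x$rhat[!grepl("^alpha\\[", names(x$rhat))], na.rm = TRUE)))
  invisible(x)
}

#' Check MCMC convergence
#'
#' Computes split-\eqn{\hat R} for every monitored parameter and compares it
#' with a threshold. Degenerate parameters (zero posterior variance) are
#' flagged separately since \eqn{\hat R} is undefined for them.
#'
#' @param fit an `occu_fit`.
#' @param threshold convergence threshold (default 1.05).
#' @return list with `rhat` (named vector), `threshold`, `degenerate`
#'   (parameter names with zero variance), and `pass` (all finite Rhat below
#'   threshold and nothing degenerate).
#' @export
check_convergence <- function(fit, threshold = 1.05) {
  if (fit$n_chains < 2L)
    stop_("Rhat requires at least 2 chains")
  rhat <- fit$rhat
  degenerate <- names(rhat)[is.nan(rhat)]
  ok <- rhat[!is.nan(rhat)]
  list(rhat = rhat, threshold = threshold, degenerate = degenerate,
       pass = length(degenerate) == 0 && all(ok < threshold))
}

#' Posterior summaries including derived habitat-use and detection means
#'
#' Summarizes every model parameter (posterior mean, SD, percentile 95% CI)
#' together with the derived quantities `habitat_use` (per-draw mean over
#' sites of \eqn{\psi_i}) and `detection` (per-draw mean of \eqn{p_{it}}
#' over surveyed site-occasions).
#'
#' @param fit an `occu_fit`.
#' @param include_random include the per-station intercepts in the table.
#' @return data frame with columns `parameter`, `mean`, `sd`, `lo`, `hi`.
#' @export
summarize_posterior <- function(fit, include_random = FALSE) {
  d <- fit$draws
  if (!include_random)
    d <- d[, !grepl("^alpha\\[", colnames(d)), drop = FALSE]
  psi_bar <- colMeans(psi_draws_(fit))
  p_bar <- p_draws_mean_(fit)
  d <- cbind(d, habitat_use = psi_bar, detection = p_bar)
  qs <- apply(d, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(parameter = colnames(d),
                    mean = unname(colMeans(d)),
                    sd = unname(apply(d, 2, sd)),
                    lo = qs[1, ], hi = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  stopifnot(all(out$lo <= out$hi))
  out
}

#' @export
summary.occu_fit <- function(object, ...) summarize_posterior(object, ...)
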