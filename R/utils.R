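# internal numeric and validation helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp over two vectors (stable log(exp(a)+exp(b)))
log_add <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

#' Split-half potential scale reduction factor
#'
#' Computes the split-\eqn{\hat R} convergence diagnostic: each chain is cut
#' in half and the classical between/within variance ratio is taken over the
#' resulting half-chains, so within-chain trends are penalized as well as
#' between-chain disagreement.
#'
#' @param x numeric matrix of posterior draws, iterations x chains.
#' @return a single \eqn{\hat R} value; `NaN` when the draws are degenerate
#'   (zero variance everywhere).
#' @keywords internal
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (!is.finite(W) || W == 0) return(NaN)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# evaluate an expression under a fixed RNG seed, restoring RNG state after
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# inverse-CDF sampler for a truncated normal; deterministic given RNG state
rtruncnorm_ <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  qnorm(u, mean, sd)
}

# mean and sd of a normal(mu, sigma) truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  da <- dnorm(al); db <- dnorm(be)
  m <- mu + sigma * (da - db) / Z
  t1 <- ifelse(is.finite(al), al * da, 0)
  t2 <- ifelse(is.finite(be), be * db, 0)
  v <- sigma^2 * (1 + (t1 - t2) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# find (mu, sigma) of the parent normal such that the [a,b]-truncated
# distribution has the requested mean and sd; identity when truncation is
# negligible (bounds beyond ~6 parent sd)
truncnorm_match <- function(target_mean, target_sd, a, b) {
  if ((a == -Inf || (target_mean - a) / target_sd > 6) &&
      (b == Inf || (b - target_mean) / target_sd > 6))
    return(c(mu = target_mean, sigma = target_sd))
  obj <- function(par) {
    mom <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mom["mean"] - target_mean)^2 / target_sd^2 +
      (mom["sd"] - target_sd)^2 / target_sd^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}
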