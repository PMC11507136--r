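# Internal helpers: argument checking and truncated-normal machinery shared by
# the cohort generator (ages, ZBI-12 raw scores).

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort_param("`%s` must be a probability in [0, 1], got %s", name,
                paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    abort_param("`%s` must be nonnegative, got %s", name,
                paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    abort_param("`%s` must be a single nonnegative integer", name)
  }
  invisible(as.integer(x))
}

check_choice <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    abort_param("`%s` must be one of: %s", name, paste(choices, collapse = ", "))
  }
  invisible(x)
}

#' Moments of a truncated normal distribution
#'
#' Mean and standard deviation of a normal distribution with latent mean `mu`
#' and latent standard deviation `sigma`, truncated to `[lower, upper]`.
#'
#' @keywords internal
#' @noRd
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  # tail-stable normalizing mass: work in the upper tail when both
  # standardized bounds are positive, where pnorm(b) - pnorm(a) cancels
  z <- if (a > 0) {
    stats::pnorm(a, lower.tail = FALSE) - stats::pnorm(b, lower.tail = FALSE)
  } else {
    stats::pnorm(b) - stats::pnorm(a)
  }
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

# Latent mu giving a requested truncated mean at fixed sigma. The truncated
# mean is strictly increasing in mu, so uniroot on a generous bracket is safe.
solve_truncnorm_mu <- function(target_mean, sigma, lower, upper) {
  if (target_mean <= lower || target_mean >= upper) {
    abort_param("target mean %.3f must lie strictly inside [%.3f, %.3f]",
                target_mean, lower, upper)
  }
  f <- function(mu) truncnorm_moments(mu, sigma, lower, upper)$mean - target_mean
  # Bracket chosen so the standardized bounds stay below ~35 in magnitude,
  # where pnorm/dnorm are still representable: inside [lower, upper] the
  # truncation keeps at least half the mass, and beyond it we never move the
  # latent mean more than 35 sigma past a bound.
  lo <- min(lower, upper - 35 * sigma)
  hi <- max(upper, lower + 35 * sigma)
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
}

#' Calibrate a truncated normal to target moments
#'
#' Finds latent `(mu, sigma)` such that the normal truncated to
#' `[lower, upper]` has mean exactly `target_mean` and standard deviation as
#' close as possible to `target_sd`. The mean is matched exactly (profiled via
#' root finding at every candidate sigma); the SD is matched by a bounded 1-D
#' optimisation, because a truncated normal on a finite interval cannot reach
#' arbitrarily large spreads.
#'
#' @keywords internal
#' @noRd
fit_truncnorm <- function(target_mean, target_sd, lower, upper) {
  width <- upper - lower
  obj <- function(log_sigma) {
    sigma <- exp(log_sigma)
    mu <- tryCatch(solve_truncnorm_mu(target_mean, sigma, lower, upper),
                   error = function(e) NA_real_)
    if (is.na(mu)) return(Inf)
    (truncnorm_moments(mu, sigma, lower, upper)$sd - target_sd)^2
  }
  opt <- stats::optimize(obj, interval = log(c(width / 100, 5 * width)),
                         tol = 1e-10)
  sigma <- exp(opt$minimum)
  mu <- solve_truncnorm_mu(target_mean, sigma, lower, upper)
  mom <- truncnorm_moments(mu, sigma, lower, upper)
  list(mu = mu, sigma = sigma, mean = mom$mean, sd = mom$sd)
}

# Exact inverse-CDF sampler; deterministic under set.seed and vectorised.
rtruncnorm <- function(n, mu, sigma, lower, upper) {
  plo <- stats::pnorm(lower, mu, sigma)
  phi <- stats::pnorm(upper, mu, sigma)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mu, sigma)
  pmin(pmax(q, lower), upper)
}
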