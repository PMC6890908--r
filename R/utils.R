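#' @keywords internal
"_PACKAGE"

# shared cache for template voxelizations and blurred bases
.datspect_cache <- new.env(parent = emptyenv())

#' Round half away from zero
#'
#' Decimal rounding in the half-up convention used for percentage tables
#' (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_num <- function(x, name, positive = FALSE,
                                   nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

## Truncated normal (lower bound only) ---------------------------------------

# quantile of N(mean, sd) truncated to [lower, Inf)
qtruncnorm_lower <- function(p, mean, sd, lower = 0) {
  a <- stats::pnorm(lower, mean, sd)
  stats::qnorm(a + p * (1 - a), mean, sd)
}

# mean and sd of N(mu, sigma) truncated to [lower, Inf)
truncnorm_moments <- function(mu, sigma, lower = 0) {
  alpha <- (lower - mu) / sigma
  # Mills ratio lambda = phi(alpha) / (1 - Phi(alpha)), computed stably
  lambda <- exp(stats::dnorm(alpha, log = TRUE) -
                  stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + alpha * lambda - lambda^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# parent-normal parameters whose zero-truncated moments match (m, s);
# falls back to the untruncated parameters when truncation is negligible
truncnorm_match <- function(m, s, lower = 0) {
  stopifnot(m > lower, s > 0)
  if (stats::pnorm(lower, m, s) < 1e-6) {
    return(c(mu = m, sigma = s))
  }
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lower)
    (mo["mean"] - m)^2 + (mo["sd"] - s)^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}
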