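#' Round monetary values half-up
#'
#' Commercial (half-up) rounding to a fixed number of decimals. Used whenever
#' euro amounts are printed or compared against published tables; all internal
#' arithmetic is carried out at full double precision and rounded only on
#' output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, euro cents).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_money(2.125)  # 2.13, not banker's 2.12
#' @export
round_money <- function(x, digits = 2) {
  stopifnot(is.numeric(x))
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5 + 1e-9) / pow
}

## Truncated-normal sampler via inverse-CDF; vectorised over mu/sd.
rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (all(sd == 0)) {
    return(pmin(pmax(rep_len(mean, n), lower), upper))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## Mean of a normal(mu, sd) truncated to [lower, upper]. When mu sits so far
## outside the interval that the tail mass underflows, the truncated mass
## collapses onto the nearer bound.
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- pnorm(b) - pnorm(a)
  if (z <= 0 || !is.finite(z)) {
    return(if (mu < lower) lower else upper)
  }
  out <- mu + sd * (dnorm(a) - dnorm(b)) / z
  if (!is.finite(out)) {
    return(if (mu < lower) lower else upper)
  }
  out
}

## Location parameter mu such that the truncated normal's realised mean hits
## `target`; the realised mean is strictly increasing in mu, so a bracket
## expanded outwards from `target` always contains the root for target inside
## (lower, upper).
truncnorm_mu_for_mean <- function(target, sd, lower, upper) {
  if (sd == 0) {
    return(target)
  }
  stopifnot(target > lower, target < upper)
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target
  lo <- target - sd
  step <- sd
  while (f(lo) > 0) {
    lo <- lo - step
    step <- step * 2
  }
  hi <- target + sd
  step <- sd
  while (f(hi) < 0) {
    hi <- hi + step
    step <- step * 2
  }
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
}

## Beta draw matched to (mean, sd) by the method of moments.
## sd = 0 degenerates to the mean; infeasible variance is an error naming the
## parameter so mis-specified dispersion never passes silently.
rbeta_ms <- function(n, mean, sd, what = "parameter") {
  if (sd == 0 || mean <= 0 || mean >= 1) {
    return(rep_len(mean, n))
  }
  vmax <- mean * (1 - mean)
  if (sd^2 >= vmax) {
    stop("beta dispersion infeasible for ", what,
         ": sd^2 = ", signif(sd^2, 4), " >= mean*(1-mean) = ", signif(vmax, 4),
         call. = FALSE)
  }
  nu <- vmax / sd^2 - 1
  rbeta(n, mean * nu, (1 - mean) * nu)
}

## Gamma draw with given mean and coefficient of variation; mean 0 or cv 0
## degenerate to the mean (structural zeros stay zero).
rgamma_cv <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) {
    return(rep_len(mean, n))
  }
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape / mean)
}

## Dirichlet draw with mean vector p and concentration (effective sample size)
## kappa; kappa = Inf degenerates to p, zeros in p are structural.
rdirichlet1 <- function(p, kappa) {
  if (!is.finite(kappa)) {
    return(p)
  }
  g <- ifelse(p > 0, rgamma(length(p), shape = p * kappa, rate = 1), 0)
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
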