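# Closed-form core of the observer models: normal-normal integration on the
# 0-100 visual analogue scale (VAS), the alpha reparameterisation of the
# variance ratio, linear habituation, the dynamic unpredictable-condition
# prior, and truncated-normal moments and sampling.

#' Normal-normal integration of a prior with one sensory observation
#'
#' Combines a Gaussian prior expectation `N(mu0, tau0^2)` with a Gaussian
#' likelihood `N(y, sigma^2)` into the Gaussian posterior. The posterior mean
#' is the precision-weighted average of prior mean and observation; the
#' posterior precision is the sum of the two precisions, so the posterior
#' standard deviation is always smaller than either input.
#'
#' @param mu0 Prior mean (VAS units). Vectorised.
#' @param tau0 Prior standard deviation (VAS units, > 0).
#' @param y Likelihood (sensory) mean (VAS units).
#' @param sigma Likelihood standard deviation (VAS units, > 0).
#'
#' @return A tibble with columns `mu1` (posterior mean) and `tau1`
#'   (posterior standard deviation), one row per input element.
#' @examples
#' integrate_normal(50, 10, 70, 10) # equal precision: mu1 = 60
#' @export
integrate_normal <- function(mu0, tau0, y, sigma) {
  if (any(tau0 <= 0) || any(sigma <= 0)) {
    stop("`tau0` and `sigma` must be strictly positive.", call. = FALSE)
  }
  p0 <- 1 / tau0^2
  pl <- 1 / sigma^2
  tibble::tibble(
    mu1  = (p0 * mu0 + pl * y) / (p0 + pl),
    tau1 = sqrt(1 / (p0 + pl))
  )
}

#' Likelihood weight implied by prior and likelihood variances
#'
#' The posterior mean of a normal-normal integration can be written as
#' `mu0 + alpha * (y - mu0)` with `alpha = tau0^2 / (sigma^2 + tau0^2)`.
#' `alpha` near 1 means the observation dominates; near 0 the prior dominates.
#'
#' @param tau0_sq Prior variance (VAS^2, >= 0).
#' @param sigma_sq Likelihood variance (VAS^2, >= 0). Both zero is an error.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
alpha_from_variances <- function(tau0_sq, sigma_sq) {
  if (any(tau0_sq < 0) || any(sigma_sq < 0)) {
    stop("Variances must be non-negative.", call. = FALSE)
  }
  if (any(tau0_sq + sigma_sq == 0)) {
    stop("`tau0_sq` and `sigma_sq` cannot both be zero.", call. = FALSE)
  }
  tau0_sq / (sigma_sq + tau0_sq)
}

#' Shrink a prior mean towards an observation
#'
#' `mu1 = mu0 + alpha * (y - mu0)`: the convex combination of prior mean and
#' observation used by all expectation-integration model variants for
#' unpredictable trials (and, in the multi-alpha variants, everywhere).
#'
#' @param mu0 Prior mean (VAS units).
#' @param alpha Likelihood weight in `[0, 1]`.
#' @param y Observation / likelihood mean (VAS units).
#' @return Numeric vector of posterior means, each between `mu0` and `y`.
#' @export
shrink_mean <- function(mu0, alpha, y) {
  if (any(alpha < 0 | alpha > 1)) {
    stop("`alpha` must lie in [0, 1].", call. = FALSE)
  }
  mu0 + alpha * (y - mu0)
}

#' Habituation-adjusted likelihood mean
#'
#' Subtracts a linear per-trial drift from the nominal VAS target:
#' `y_t = y_i - h * t`. Positive `h` models habituation (stimuli feel weaker
#' over a run), negative `h` sensitisation.
#'
#' @param y_i Nominal VAS target of the trial (30, 50 or 70 in the task).
#' @param h Drift in VAS units per trial.
#' @param t Trial index within the run (1-based).
#' @return Numeric vector `y_i - h * t`.
#' @export
habituated_mean <- function(y_i, h, t) {
  y_i - h * t
}

#' Dynamic prior mean for unpredictable trials
#'
#' In the unpredictable condition the observer cannot see which intensity is
#' coming, but the schedule guarantees five stimuli per level and run. The
#' dynamic prior tracks the remaining occurrences: each level is weighted by
#' `remaining_count / remaining_trials` and the weighted average of the
#' per-level prior means is the trial's expected intensity. At trial 1 every
#' weight is 5/15 = 1/3; after a streak of one level the expectation drifts
#' away from it.
#'
#' @param remaining_counts Named or ordered numeric vector of remaining
#'   occurrences per level (non-negative, not all zero).
#' @param mu0_by_level Prior means per level, same order as
#'   `remaining_counts`.
#' @return The weighted prior mean (scalar, within the range of
#'   `mu0_by_level`).
#' @examples
#' dynamic_prior_mean(c(5, 5, 5), c(30, 50, 70)) # 50
#' dynamic_prior_mean(c(5, 5, 2), c(30, 50, 70)) # 45
#' @export
dynamic_prior_mean <- function(remaining_counts, mu0_by_level) {
  if (length(remaining_counts) != length(mu0_by_level)) {
    stop("`remaining_counts` and `mu0_by_level` must have equal length.",
         call. = FALSE)
  }
  if (any(remaining_counts < 0)) {
    stop("Remaining counts must be non-negative.", call. = FALSE)
  }
  total <- sum(remaining_counts)
  if (total == 0) {
    stop("At least one remaining count must be positive.", call. = FALSE)
  }
  sum(remaining_counts / total * mu0_by_level)
}

# stable Phi(b) - Phi(a) for a <= b (standardised truncation bounds)
.norm_mass <- function(a, b) {
  ifelse(a > 0, pnorm(-a) - pnorm(-b), pnorm(b) - pnorm(a))
}

#' Truncated-normal density, distribution, quantile, moments and sampling
#'
#' The rating model treats each rating as a draw from a normal distribution
#' truncated to the VAS scale `[lo, hi]` (truncation, not censoring: mass
#' outside the scale is renormalised away, so ratings at the bounds carry the
#' truncated density there). `rtrunc_normal()` samples by inverse-CDF, so it
#' never loops even when `mu` lies far outside the scale.
#'
#' @param x,q,p,n Usual density/distribution/quantile/sample arguments.
#' @param mu Location of the untruncated normal (VAS units; may lie outside
#'   `[lo, hi]`).
#' @param sd Scale of the untruncated normal (> 0).
#' @param lo,hi Truncation bounds, default the VAS scale `[0, 100]`.
#' @param log Return log density?
#' @return `dtrunc_normal()`/`ptrunc_normal()`/`qtrunc_normal()` numeric
#'   vectors; `rtrunc_normal()` draws in `[lo, hi]`; `trunc_normal_mean()`
#'   the exact mean of the truncated distribution.
#' @name trunc_normal
NULL

#' @rdname trunc_normal
#' @export
dtrunc_normal <- function(x, mu, sd, lo = 0, hi = 100, log = FALSE) {
  if (any(sd <= 0)) stop("`sd` must be positive.", call. = FALSE)
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lz <- log(.norm_mass(a, b))
  ld <- dnorm(x, mu, sd, log = TRUE) - lz
  ld[x < lo | x > hi] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname trunc_normal
#' @export
ptrunc_normal <- function(q, mu, sd, lo = 0, hi = 100) {
  if (any(sd <= 0)) stop("`sd` must be positive.", call. = FALSE)
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- .norm_mass(a, b)
  p <- (pnorm(pmin(pmax((q - mu) / sd, a), b)) - pnorm(a)) / z
  pmin(pmax(p, 0), 1)
}

#' @rdname trunc_normal
#' @export
qtrunc_normal <- function(p, mu, sd, lo = 0, hi = 100) {
  if (any(sd <= 0)) stop("`sd` must be positive.", call. = FALSE)
  n <- max(length(p), length(mu), length(sd), length(lo), length(hi))
  p <- rep_len(p, n); mu <- rep_len(mu, n); sd <- rep_len(sd, n)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  # work in the better-conditioned tail: reflect when the mass sits high
  flip <- a > 0
  aa <- ifelse(flip, -b, a)
  bb <- ifelse(flip, -a, b)
  pp <- ifelse(flip, 1 - p, p)
  z <- pnorm(bb) - pnorm(aa)
  x <- qnorm(pnorm(aa) + pp * z)
  x <- ifelse(flip, -x, x)
  pmin(pmax(mu + sd * x, lo), hi)
}

#' @rdname trunc_normal
#' @export
rtrunc_normal <- function(n, mu, sd, lo = 0, hi = 100) {
  qtrunc_normal(runif(n), mu, sd, lo = lo, hi = hi)
}

#' @rdname trunc_normal
#' @export
trunc_normal_mean <- function(mu, sd, lo = 0, hi = 100) {
  if (any(sd <= 0)) stop("`sd` must be positive.", call. = FALSE)
  if (any(lo >= hi)) stop("`lo` must be smaller than `hi`.", call. = FALSE)
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- .norm_mass(a, b)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}
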