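# Closed-form integration core and truncated-normal machinery.

test_that("normal-normal integration matches the analytic solution", {
  eq <- integrate_normal(50, 10, 70, 10)
  expect_equal(eq$mu1, 60)
  expect_equal(eq$tau1, sqrt(50))

  agree <- integrate_normal(42, 3.7, 42, 19)
  expect_equal(agree$mu1, 42)

  flat <- integrate_normal(50, 1e6, 70, 10)
  expect_lt(abs(flat$mu1 - 70), 1e-3)

  expect_error(integrate_normal(50, 0, 70, 10), "positive")
  expect_error(integrate_normal(50, 10, 70, -1), "positive")
})

test_that("posterior SD beats both prior and likelihood SD", {
  set.seed(42)
  tau0 <- exp(rnorm(100, 1, 1))
  sigma <- exp(rnorm(100, 1, 1))
  out <- integrate_normal(runif(100, 0, 100), tau0, runif(100, 0, 100),
                          sigma)
  expect_true(all(out$tau1 <= pmin(tau0, sigma) + 1e-12))
})

test_that("variance-ratio weight behaves as a convex weight", {
  expect_equal(alpha_from_variances(4, 4), 0.5)
  expect_equal(alpha_from_variances(3, 1), 0.75)
  expect_equal(alpha_from_variances(0, 5), 0)
  expect_error(alpha_from_variances(0, 0), "zero")
})

test_that("shrinkage form and precision-weighting form are the same model", {
  expect_equal(shrink_mean(50, 0, 70), 50)
  expect_equal(shrink_mean(50, 1, 70), 70)
  expect_equal(shrink_mean(50, 0.74, 70), 64.8)
  expect_error(shrink_mean(50, 1.2, 70), "0, 1")

  set.seed(7)
  n <- 10000
  mu0 <- runif(n, 0, 100); y <- runif(n, 0, 100)
  tau0 <- exp(runif(n, -2, 4)); sigma <- exp(runif(n, -2, 4))
  direct <- integrate_normal(mu0, tau0, y, sigma)$mu1
  via_alpha <- shrink_mean(mu0, alpha_from_variances(tau0^2, sigma^2), y)
  expect_lt(max(abs(direct - via_alpha)), 1e-10)
})

test_that("habituation is a linear per-trial drift", {
  expect_equal(habituated_mean(70, 0, 9), 70)
  expect_equal(habituated_mean(70, 1, 5), 65)
  expect_equal(habituated_mean(30, -0.5, 4), 32) # sensitisation
})

test_that("dynamic prior weights are remaining counts over remaining trials", {
  expect_equal(dynamic_prior_mean(c(5, 5, 5), c(30, 50, 70)), 50)
  expect_equal(dynamic_prior_mean(c(5, 5, 2), c(30, 50, 70)), 45)
  expect_equal(dynamic_prior_mean(c(0, 0, 1), c(30, 50, 70)), 70)
  expect_error(dynamic_prior_mean(c(0, 0, 0), c(30, 50, 70)), "positive")
  expect_error(dynamic_prior_mean(c(-1, 2, 3), c(30, 50, 70)),
               "non-negative")

  # permutation invariance and range containment
  set.seed(1)
  for (i in 1:50) {
    counts <- sample(0:5, 3, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    mus <- runif(3, 0, 100)
    m <- dynamic_prior_mean(counts, mus)
    expect_gte(m, min(mus))
    expect_lte(m, max(mus))
    perm <- sample(3)
    expect_equal(dynamic_prior_mean(counts[perm], mus[perm]), m)
  }
})

test_that("truncated-normal mean matches a quadrature oracle", {
  expect_equal(trunc_normal_mean(50, 10), 50)
  expect_equal(trunc_normal_mean(50, 123), 50)
  # degenerate limit
  expect_lt(abs(trunc_normal_mean(30, 1e-4) - 30), 1e-6)

  # quadrature on the standardised scale; cases whose truncation mass
  # underflows double precision are outside any quadrature oracle's reach
  oracle <- function(mu, sd) {
    a <- -mu / sd; b <- (100 - mu) / sd
    z <- integrate(function(v) dnorm(v), a, b, rel.tol = 1e-12)$value
    mu + sd * integrate(function(v) v * dnorm(v) / z, a, b,
                        rel.tol = 1e-12)$value
  }
  grid <- expand.grid(mu = c(-20, 5, 30, 50, 70, 95, 120),
                      sd = c(1, 5, 12, 30))
  grid <- grid[pnorm((100 - grid$mu) / grid$sd) -
                 pnorm(-grid$mu / grid$sd) > 1e-10, ]
  for (i in seq_len(nrow(grid))) {
    expect_lt(abs(trunc_normal_mean(grid$mu[i], grid$sd[i]) -
                    oracle(grid$mu[i], grid$sd[i])), 1e-6)
  }

  # dispersion biases ratings towards the scale centre
  expect_gt(trunc_normal_mean(30, 25), trunc_normal_mean(30, 5))
  expect_lt(trunc_normal_mean(70, 25), trunc_normal_mean(70, 5))
})

test_that("truncated-normal density normalises and sampling is rejection-free", {
  z <- integrate(function(x) dtrunc_normal(x, 64, 17), 0, 100)$value
  expect_lt(abs(z - 1), 1e-6)
  # near-uniform limit: log density approaches log(1/100)
  expect_lt(abs(dtrunc_normal(37, 50, 1e5, log = TRUE) - log(1 / 100)),
            1e-3)
  expect_identical(dtrunc_normal(-1, 50, 10), 0)

  set.seed(3)
  x <- rtrunc_normal(1e5, 50, 10)
  expect_true(all(x >= 0 & x <= 100))
  expect_lt(abs(mean(x) - 50), 0.1)

  # mean far outside the scale: inverse-CDF still yields valid draws
  y <- rtrunc_normal(1000, 120, 10)
  expect_true(all(is.finite(y) & y >= 0 & y <= 100))
  expect_gt(min(y), 70)
  # empirical mean tracks the closed-form mean
  expect_lt(abs(mean(y) - trunc_normal_mean(120, 10)), 0.3)

  # scalar parameters with vector probabilities recycle correctly
  q <- qtrunc_normal(c(0.25, 0.5, 0.75), 50, 10)
  expect_length(q, 3)
  expect_equal(q[2], 50)
  expect_equal(ptrunc_normal(q, 50, 10), c(0.25, 0.5, 0.75),
               tolerance = 1e-10)
})
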