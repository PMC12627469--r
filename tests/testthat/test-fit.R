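# Hierarchical fitting, HPDI, posterior prediction, recovery.

test_that("hpdi equals the brute-force minimal-window oracle", {
  brute <- function(x, mass) {
    x <- sort(x)
    n <- length(x)
    m <- ceiling(mass * n)
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - m + 1)) {
      wdt <- x[i + m - 1] - x[i]
      if (wdt < best[1] - 1e-15) best <- c(wdt, x[i], x[i + m - 1])
    }
    c(lo = best[2], hi = best[3])
  }
  expect_equal(hpdi(1:100, 0.95), c(lo = 1, hi = 95))
  expect_equal(hpdi(c(5, 1), 0.5), c(lo = 1, hi = 1))
  expect_error(hpdi(1:10, 1.2), "0, 1")
  expect_error(hpdi(3), "2 draws")

  set.seed(31)
  for (i in 1:60) {
    x <- switch(1 + i %% 3, rnorm(sample(5:300, 1)),
                rexp(sample(5:300, 1)), runif(sample(5:300, 1)))
    mass <- runif(1, 0.2, 0.99)
    expect_equal(hpdi(x, mass), brute(x, mass))
  }

  # symmetric unimodal: HPDI close to the central interval
  set.seed(32)
  x <- rnorm(20000)
  h <- hpdi(x)
  q <- quantile(x, c(0.025, 0.975))
  expect_lt(max(abs(h - q)), 0.12)
  # mass -> 1 approaches the sample range
  expect_equal(unname(hpdi(x, 0.9999)[1]), sort(x)[2])
})

test_that("near-degenerate data pins the null model's noise and target", {
  sim <- simulate_dataset(
    "null_hab", n_subjects = 1,
    group = list(noise = 0.5, log_sd = 0, h = 0, h_sd = 0), seed = 41)
  fit <- fit_hierarchical(sim, model_spec("null_hab", mcmc = test_mcmc()),
                          seed = 42)
  sp <- subject_parameters(fit)
  expect_lt(sp$noise, 1)
  expect_lt(abs(sp$h), 0.05)
  pp <- posterior_predict(fit, ndraws = 100, seed = 1)
  cell <- pp |>
    dplyr::group_by(intensity_level) |>
    dplyr::summarise(m = mean(prediction))
  expect_lt(max(abs(cell$m - cell$intensity_level)), 1)
})

test_that("fitting is deterministic under a fixed seed", {
  sim <- simulate_dataset("null_hab", n_subjects = 1, seed = 43)
  spec <- model_spec("null_hab", mcmc = test_mcmc(chains = 2, iter = 300,
                                                  warmup = 150,
                                                  adapt = 100))
  f1 <- fit_hierarchical(sim, spec, seed = 7)
  f2 <- fit_hierarchical(sim, spec, seed = 7)
  expect_identical(lapply(f1$draws, as.matrix), lapply(f2$draws, as.matrix))
})

test_that("condition-specific prior SDs are recovered subject by subject", {
  sim <- simulate_dataset("precision_change_dynamic", n_subjects = 6,
                          seed = 44)
  fit <- fit_hierarchical(
    sim, model_spec("precision_change_dynamic",
                    mcmc = test_mcmc(chains = 2, iter = 700, warmup = 350)),
    seed = 45)
  sp <- subject_parameters(fit)
  # generated with tau0_C = 3 << tau0_P = 8
  expect_gte(mean(sp$tau0_C < sp$tau0_P), 0.9)
  truth <- true_parameters(sim)
  expect_gt(cor(truth$alpha_U, sp$alpha_U), 0)
})

test_that("posterior predictions stay on scale and track cell means", {
  sim <- simulate_dataset("precision_change_dynamic", n_subjects = 4,
                          seed = 46)
  fit <- fit_hierarchical(
    sim, model_spec("precision_change_dynamic", mcmc = test_mcmc()),
    seed = 47)
  pp <- posterior_predict(fit, ndraws = 150, seed = 2)
  expect_true(all(pp$prediction >= 0 & pp$prediction <= 100))
  obs <- sim |>
    dplyr::group_by(condition, intensity_level) |>
    dplyr::summarise(m = mean(rating), .groups = "drop")
  pred <- pp |>
    dplyr::group_by(condition, intensity_level) |>
    dplyr::summarise(m = mean(prediction), .groups = "drop")
  expect_lt(max(abs(obs$m - pred$m)), 3)
})

test_that("loglik matrix aligns with the scored trials", {
  sim <- simulate_dataset("null_hab", n_subjects = 2, p_timeout = 0.1,
                          seed = 48)
  fit <- fit_hierarchical(sim, model_spec("null_hab", mcmc = test_mcmc()),
                          seed = 49)
  ll <- loglik_matrix(fit, ndraws = 120)
  expect_equal(ncol(ll), sum(!is.na(sim$rating)))
  expect_equal(nrow(fit$trials), ncol(ll))
  expect_true(all(is.finite(ll)))
})

test_that("null-model noise recovers almost perfectly at moderate n", {
  rec <- parameter_recovery("null_hab", n_subjects = 12,
                            mcmc = test_mcmc(), seed = 50)
  r_noise <- rec$table$r[rec$table$parameter == "noise"]
  expect_gt(r_noise, 0.9)
})

test_that("tidy and glance summarise fits coherently", {
  sim <- simulate_dataset("null_hab", n_subjects = 2, seed = 51)
  fit <- fit_hierarchical(sim, model_spec("null_hab", mcmc = test_mcmc()),
                          seed = 52)
  td <- tidy(fit)
  expect_true(all(c("term", "mean", "hpdi_lo", "hpdi_hi", "rhat", "ess")
                  %in% names(td)))
  expect_true(all(td$hpdi_lo <= td$mean & td$mean <= td$hpdi_hi))
  gl <- glance(fit)
  expect_equal(gl$n_trials, 180)
  expect_equal(gl$chains, 2)
})
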