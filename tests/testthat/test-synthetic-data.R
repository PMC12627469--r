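# Schedule generation, parameter sampling, and dataset simulation.

test_that("controllable sequences always satisfy the 5-per-level constraint", {
  for (seed in 1:25) {
    s <- generate_controllable_sequence(choice_bias = runif(1, 0, 5),
                                        seed = seed)
    expect_equal(as.numeric(table(factor(s, c(30, 50, 70)))), c(5, 5, 5))
  }
})

test_that("zero choice bias gives uniform first-trial choices", {
  set.seed(2)
  first <- vapply(1:3000, function(i)
    generate_controllable_sequence(0)[1], integer(1))
  freq <- as.numeric(table(factor(first, c(30, 50, 70)))) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.035))
})

test_that("extreme choice bias front-loads the high level", {
  set.seed(3)
  heads <- vapply(1:200, function(i)
    all(generate_controllable_sequence(40)[1:5] == 70), logical(1))
  expect_gte(mean(heads), 0.99)
})

test_that("yoked matching copies a donor sequence verbatim", {
  donor <- rep(c(70, 50, 30), 5)
  expect_identical(generate_matched_sequence(donor, "yoked", seed = 1),
                   as.integer(donor))
  expect_error(generate_matched_sequence(rep(70, 15), "yoked"),
               "5-per-level")
})

test_that("probability matching respects the cap and the input frequencies", {
  set.seed(4)
  for (i in 1:20) {
    s <- generate_matched_sequence(matrix(1 / 3, 15, 3),
                                   "probability_matched")
    expect_equal(as.numeric(table(factor(s, c(30, 50, 70)))), c(5, 5, 5))
  }
  bad <- matrix(1 / 3, 15, 3); bad[1, ] <- c(0.5, 0.5, 0.5)
  expect_error(generate_matched_sequence(bad, "probability_matched"),
               "sum to 1")

  # front-loaded high-level mass -> high stimuli arrive earlier than low
  freq <- matrix(0, 15, 3)
  freq[, 3] <- seq(0.8, 0.05, length.out = 15)
  freq[, 1] <- seq(0.05, 0.8, length.out = 15)
  freq[, 2] <- 1 - freq[, 1] - freq[, 3]
  pos <- t(vapply(1:1000, function(i) {
    s <- generate_matched_sequence(freq, "probability_matched")
    c(mean(which(s == 70)), mean(which(s == 30)))
  }, numeric(2)))
  expect_lt(mean(pos[, 1]), mean(pos[, 2]))
})

test_that("hyperprior draws follow the group-level prior scheme", {
  p <- sample_group_parameters("precision_change_dynamic", 4000,
                               group = "hyperprior", seed = 6)
  expect_true(all(p$alpha_U >= 0 & p$alpha_U <= 1))
  # log tau0 ~ N(1.5, 0.5) -> median exp(1.5)
  expect_lt(abs(median(p$tau0_C) - exp(1.5)), 0.15)
  expect_lt(abs(median(p$tau1) - exp(1.5)), 0.15)
})

test_that("fixed group values with zero spread give identical subjects", {
  p <- sample_group_parameters(
    "precision_change_dynamic", 5,
    group = list(sigma_mu0 = 0, alpha_sd = 0, h_sd = 0, log_sd = 0),
    seed = 1)
  for (col in setdiff(names(p), "subject_id")) {
    expect_equal(length(unique(p[[col]])), 1)
  }
})

test_that("a noise-free null model reproduces the VAS targets", {
  sim <- simulate_dataset(
    "null_hab", n_subjects = 2,
    group = list(noise = 1e-6, log_sd = 0, h = 0, h_sd = 0), seed = 8)
  expect_lt(max(abs(sim$rating - sim$intensity_level)), 1e-4)
})

test_that("generated ratings always stay on the VAS scale", {
  for (v in c("precision_change_dynamic", "mean_shift_fixed", "null_hab",
              "three_alpha")) {
    sim <- simulate_dataset(v, n_subjects = 3, seed = 9)
    expect_true(all(sim$rating >= 0 & sim$rating <= 100))
    expect_silent(validate_trials(sim))
  }
})

test_that("precision change in generation shows up in the SD summaries", {
  sim <- simulate_dataset("precision_change_dynamic", n_subjects = 15,
                          seed = 10)
  tab <- within_subject_sd_table(sim) |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(sd))
  expect_lt(tab$m[tab$condition == "C"], tab$m[tab$condition == "P"])
  expect_lt(tab$m[tab$condition == "P"], tab$m[tab$condition == "U"])
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_dataset(n_subjects = 2, seed = 12)
  b <- simulate_dataset(n_subjects = 2, seed = 12)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(true_parameters(a), true_parameters(b))
})

test_that("the mixed-model generator anchors at the observed cell means", {
  d <- simulate_lmm_dataset(200, effect = 0.29, subject_sd = 0,
                            resid_sd = 1e-3, seed = 13)
  cells <- d |>
    dplyr::group_by(condition, intensity_level) |>
    dplyr::summarise(m = mean(rating), .groups = "drop")
  get <- function(cond, lev) cells$m[cells$condition == cond &
                                       cells$intensity_level == lev]
  # low intensity: unpredictable rated higher; high intensity: reversed
  expect_gt(get("U", 30), get("C", 30))
  expect_gt(get("C", 70), get("U", 70))
  # implied interaction equals the requested effect
  slope <- function(cond) (get(cond, 70) - get(cond, 30)) / 40
  expect_equal(slope("C") - slope("U"), 0.29, tolerance = 1e-3)
})

test_that("power is degenerate for a single replicate", {
  pw <- simulate_power(6, effect = 0.8, reps = 1, seed = 3, mcmc = list(
    chains = 1, iter = 300, warmup = 150, adapt = 100))
  expect_true(pw$power %in% c(0, 1))
})
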