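# Bayesian regressions on ratings, rating SDs and choice frequencies.

test_that("choice-frequency slopes mirror the generated choice pattern", {
  sim <- simulate_dataset(n_subjects = 30, seed = 71)
  cp <- choice_percentages(sim)
  f70 <- fit_choice_freq(cp, 70, 1, mcmc = test_mcmc(), seed = 1)
  f30 <- fit_choice_freq(cp, 30, 1, mcmc = test_mcmc(), seed = 1)
  s70 <- f70$coefficients[f70$coefficients$term == "trial", ]
  s30 <- f30$coefficients[f30$coefficients$term == "trial", ]
  expect_lt(s70$hpdi_hi, 0) # high level chosen early
  expect_gt(s30$hpdi_lo, 0) # low level chosen late

  # the medium level's inverted U favours the quadratic model
  f50_lin <- fit_choice_freq(cp, 50, 1, mcmc = test_mcmc(), seed = 2)
  f50_quad <- fit_choice_freq(cp, 50, 2, mcmc = test_mcmc(), seed = 2)
  expect_gt(f50_quad$elpd$elpd, f50_lin$elpd$elpd)
  quad <- f50_quad$coefficients
  expect_lt(quad$mean[quad$term == "I(trial^2)"], 0)
})

test_that("a flat choice profile yields a slope centred at zero", {
  flat <- tidyr::expand_grid(trial = 1:15,
                             intensity_level = c(30, 50, 70))
  set.seed(72)
  flat$percent <- 100 / 3 + rnorm(45, 0, 0.5)
  f <- fit_choice_freq(flat, 50, 1, mcmc = test_mcmc(), seed = 3)
  s <- f$coefficients[f$coefficients$term == "trial", ]
  expect_lt(s$hpdi_lo, 0)
  expect_gt(s$hpdi_hi, 0)
})

test_that("the rating LMM recovers a built-in interaction", {
  d <- simulate_lmm_dataset(12, effect = 0.29, seed = 73)
  fit <- fit_rating_lmm(d, baseline = "C", mcmc = test_mcmc(), seed = 4)
  cu <- fit$pairwise[fit$pairwise$term == "interaction_C_vs_U", ]
  expect_gt(cu$hpdi_lo, 0)
  expect_true(all(c("interaction_C_vs_U", "interaction_P_vs_U",
                    "interaction_C_vs_P") %in% fit$pairwise$term))
})

test_that("baseline switching leaves the implied condition slopes alone", {
  d <- simulate_lmm_dataset(10, effect = 0.4, seed = 74)
  fC <- fit_rating_lmm(d, baseline = "C", mcmc = test_mcmc(), seed = 5,
                       both_baselines = FALSE)
  fU <- fit_rating_lmm(d, baseline = "U", mcmc = test_mcmc(), seed = 6,
                       both_baselines = FALSE)
  slope <- function(fit, base) {
    co <- fit$coefficients
    s0 <- co$mean[co$term == "intensity_level"]
    out <- c(C = NA, P = NA, U = NA)
    out[base] <- s0
    for (cond in setdiff(names(out), base)) {
      nm <- sprintf("intensity_level:condition%s", cond)
      out[cond] <- s0 + co$mean[co$term == nm]
    }
    out
  }
  expect_lt(max(abs(slope(fC, "C") - slope(fU, "U"))), 0.08)
})

test_that("duplicating every row sharpens but does not move the posterior", {
  d <- simulate_lmm_dataset(8, effect = 0.5, seed = 75)
  f1 <- fit_rating_lmm(d, baseline = "U", mcmc = test_mcmc(), seed = 7,
                       both_baselines = FALSE)
  f2 <- fit_rating_lmm(dplyr::bind_rows(d, d), baseline = "U",
                       mcmc = test_mcmc(), seed = 7,
                       both_baselines = FALSE)
  t1 <- f1$coefficients[f1$coefficients$term ==
                          "intensity_level:conditionC", ]
  t2 <- f2$coefficients[f2$coefficients$term ==
                          "intensity_level:conditionC", ]
  expect_lt(abs(t1$mean - t2$mean), 0.05)
  expect_lt(t2$hpdi_hi - t2$hpdi_lo, t1$hpdi_hi - t1$hpdi_lo)
})

test_that("SD model sees the generated precision ordering, not permuted labels", {
  sim <- simulate_dataset("precision_change_dynamic", n_subjects = 12,
                          seed = 76)
  tab <- within_subject_sd_table(sim)
  fit <- fit_sd_lmm(tab, mcmc = test_mcmc(), seed = 8)
  pu <- fit$pairwise
  # generated with tau0_C < tau0_P < tau1: U has the largest dispersion
  expect_lt(pu$hpdi_hi[pu$term == "C_vs_U"], 0)
  expect_lt(pu$hpdi_hi[pu$term == "P_vs_U"], 0)
  expect_gt(pu$hpdi_lo[pu$term == "P_vs_C"], 0)

  # permuting condition labels destroys the effect
  set.seed(9)
  perm <- tab |>
    dplyr::group_by(subject_id) |>
    dplyr::mutate(condition = sample(condition)) |>
    dplyr::ungroup()
  fitp <- fit_sd_lmm(perm, mcmc = test_mcmc(), seed = 10)
  cu <- fitp$pairwise[fitp$pairwise$term == "C_vs_U", ]
  expect_lt(cu$hpdi_lo, 0)
  expect_gt(cu$hpdi_hi, 0)
})

test_that("bounded-scale dispersion produces the inverted-U SD pattern", {
  # wide noise against the scale bounds compresses SDs at the extreme
  # levels, leaving the medium level's dispersion highest
  sim <- simulate_dataset("null_hab", n_subjects = 15,
                          group = list(noise = 28, log_sd = 0), seed = 77)
  fit <- fit_sd_lmm(within_subject_sd_table(sim), mcmc = test_mcmc(),
                    seed = 11)
  pw <- fit$pairwise
  expect_gt(pw$mean[pw$term == "med_vs_low"], 0)
  expect_lt(pw$mean[pw$term == "high_vs_med"], 0)
})

test_that("within-subject SEM removes between-subject offsets", {
  cells <- tidyr::expand_grid(subject = sprintf("S%d", 1:8),
                              condition = c("C", "P", "U"))
  profile <- c(C = 9, P = 11, U = 14)
  cells$value <- profile[cells$condition]

  # identical profiles -> zero corrected SEM
  out <- within_subject_sem(cells, value, subject, condition)
  expect_equal(out$sem, rep(0, 3))

  # pure between-subject offsets -> corrected SEM 0, naive SEM > 0
  offset <- setNames(seq(0, 35, 5), sprintf("S%d", 1:8))
  cells$value <- profile[cells$condition] + offset[cells$subject]
  out2 <- within_subject_sem(cells, value, subject, condition)
  expect_lt(max(out2$sem), 1e-9)
  naive <- cells |>
    dplyr::group_by(condition) |>
    dplyr::summarise(sem = sd(value) / sqrt(dplyr::n()))
  expect_true(all(naive$sem > 1))

  # a single cell falls back to the naive SEM
  one <- dplyr::filter(cells, condition == "C")
  out3 <- within_subject_sem(one, value, subject, condition)
  expect_equal(out3$sem, naive$sem[naive$condition == "C"],
               tolerance = 1e-9)

  # incomplete grids are excluded with a warning
  expect_warning(
    within_subject_sem(cells[-1, ], value, subject, condition),
    "incomplete")
})
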