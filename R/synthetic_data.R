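# Synthetic-data generator emulating the three-condition heat-pain task:
# choice-driven controllable schedules, matched predictable/unpredictable
# schedules, subject parameters, ratings drawn from the observer models, and
# the simulation-based power analysis.

# trial-dependent utilities of the choice model: high intensities are
# preferred early (dread reduction), low ones late, medium ones mid-run
.choice_utilities <- function(t) {
  cbind(`30` = (t - 8) / 7,
        `50` = 2 * ((7 - abs(t - 8)) / 7) - 1,
        `70` = (8 - t) / 7)
}

#' Generate one controllable-run intensity sequence
#'
#' Emulates choice behaviour in the controllable condition: at each of 15
#' trials the subject picks one of the levels that still have stimuli left
#' (each level must be chosen exactly five times per run) with softmax
#' probabilities over linear trial-dependent utilities -- high intensity
#' preferred early, low late, medium mid-run. `choice_bias = 0` gives uniform
#' choices over the feasible levels; larger values sharpen the early-high /
#' late-low pattern. The default reproduces the sign and approximate size of
#' the observed choice-frequency slopes (about -3.6 percentage points per
#' trial for the high level, +3 for the low level).
#'
#' @param choice_bias Non-negative softmax scale of the utilities.
#' @param seed Optional integer seed.
#' @return Integer vector of 15 levels (values 30/50/70), five of each.
#' @export
generate_controllable_sequence <- function(choice_bias = 0.8, seed = NULL) {
  if (choice_bias < 0) stop("`choice_bias` must be >= 0.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  remaining <- c(`30` = 5L, `50` = 5L, `70` = 5L)
  out <- integer(15)
  u <- .choice_utilities(1:15)
  for (t in 1:15) {
    feasible <- remaining > 0
    w <- exp(choice_bias * u[t, ]) * feasible
    pick <- sample(c(30L, 50L, 70L), 1, prob = w / sum(w))
    remaining[as.character(pick)] <- remaining[as.character(pick)] - 1L
    out[t] <- pick
  }
  out
}

#' Generate a matched predictable/unpredictable sequence
#'
#' Matches computer-chosen sequences to controllable-condition choice
#' behaviour, the way the task's later-acquired samples were scheduled:
#' `"yoked"` returns one donor sequence verbatim; `"probability_matched"`
#' turns the donors' per-trial choice frequencies into sampling
#' probabilities, subject to the five-per-level cap (when a level is
#' exhausted, probabilities are renormalised over the remaining levels).
#'
#' @param donor Either a list/matrix of donor sequences (each 15 levels, five
#'   per level) or, for `"probability_matched"`, a 15 x 3 matrix of per-trial
#'   level probabilities (columns in order 30, 50, 70; rows must sum to 1).
#' @param method `"yoked"` or `"probability_matched"`.
#' @param seed Optional integer seed.
#' @return Integer vector of 15 levels, five of each.
#' @export
generate_matched_sequence <- function(donor,
                                      method = c("yoked",
                                                 "probability_matched"),
                                      seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  as_seq_matrix <- function(x) {
    if (is.list(x)) x <- do.call(rbind, x)
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x
  }
  if (method == "yoked") {
    seqs <- as_seq_matrix(donor)
    seqs <- seqs[sample(nrow(seqs), 1), ]
    if (!all(table(factor(seqs, levels = .intensity_levels)) == 5)) {
      stop("Donor sequence violates the 5-per-level constraint.",
           call. = FALSE)
    }
    return(as.integer(seqs))
  }
  # probability-matched
  if (is.matrix(donor) && nrow(donor) == 15 && ncol(donor) == 3 &&
      all(donor >= 0) && all(donor <= 1)) {
    freq <- donor
    if (any(abs(rowSums(freq) - 1) > 1e-8)) {
      stop("Per-trial probabilities must sum to 1.", call. = FALSE)
    }
  } else {
    seqs <- as_seq_matrix(donor)
    freq <- t(vapply(1:15, function(t) {
      tab <- table(factor(seqs[, t], levels = .intensity_levels))
      as.numeric(tab) / sum(tab)
    }, numeric(3)))
  }
  remaining <- c(5L, 5L, 5L)
  out <- integer(15)
  for (t in 1:15) {
    w <- freq[t, ] * (remaining > 0)
    if (sum(w) == 0) w <- as.numeric(remaining > 0)
    idx <- sample(1:3, 1, prob = w / sum(w))
    remaining[idx] <- remaining[idx] - 1L
    out[t] <- .intensity_levels[idx]
  }
  out
}

#' Default group-level generating parameters
#'
#' The generator's study conditions, chosen once: shared prior means at the
#' VAS targets with between-subject spread `sigma_mu0 = e^1.5`; for
#' precision-change variants a controllable prior SD of 3 versus a
#' predictable prior SD of 8; for mean-shift variants prior means pushed 3
#' VAS units towards the scale ends in the controllable condition with a
#' shared prior SD of 8; unpredictable-trial rating SD `tau1 = 12`
#' (the observed unpredictable-condition rating variability scale);
#' likelihood weight `alpha = 0.74` with between-subject SD 0.18; no mean
#' habituation (`h = 0`, subject SD 0.3); null-model noise SD 12.
#'
#' @param variant One of [model_variants()].
#' @return Named list of group values and between-subject spreads.
#' @export
default_group_parameters <- function(variant) {
  variant <- .check_variant(variant)
  info <- variant_info(variant)
  g <- list(
    mu0 = c(30, 50, 70), sigma_mu0 = exp(1.5),
    tau1 = 12, alpha = 0.74, alpha_sd = 0.18,
    h = 0, h_sd = 0.3, mu0_U = 50, mu0_U_sd = exp(1.5),
    noise = 12, log_sd = 0.2)
  if (info$free_mu0) {
    g$mu0_C <- c(27, 50, 73)
    g$mu0_P <- c(30, 50, 70)
  }
  if (info$free_tau0) {
    g$tau0_C <- 3
    g$tau0_P <- 8
  } else {
    g$tau0 <- 8
  }
  if (variant == "two_alpha") g$alpha_CP <- 0.9
  if (variant == "three_alpha") {
    g$alpha_C <- 0.9
    g$alpha_P <- 0.85
  }
  g
}

#' Sample subject-level parameters for a model variant
#'
#' Two modes. With `group = "hyperprior"`, every subject's parameters are
#' drawn directly from the model's group-level priors (per-level prior means
#' `N(30/50/70, 100)`; SD-type parameters log-normal with `log ~ N(1.5,
#' 0.5)`; likelihood weights `N(0.5, 0.3)` truncated to `[0, 1]`;
#' habituation `N(0, 1)`). With a list (defaults from
#' [default_group_parameters()], overridable entry-wise), subjects scatter
#' around fixed group values: prior means with SD `sigma_mu0`, weights with
#' SD `alpha_sd` (truncated), habituation with SD `h_sd`, SD-type parameters
#' log-normally with `log_sd`; setting every spread to 0 makes all subjects
#' identical.
#'
#' @param variant One of [model_variants()].
#' @param n_subjects Number of subjects.
#' @param group `"hyperprior"`, `NULL` (defaults), or a named list merged
#'   into the defaults.
#' @param seed Optional integer seed.
#' @return Tibble with one row per subject and the variant's parameter
#'   columns (tied parameters are stored explicitly, e.g. `mu0_P_30` equals
#'   `mu0_C_30` in precision-change variants).
#' @export
sample_group_parameters <- function(variant, n_subjects, group = NULL,
                                    seed = NULL) {
  variant <- .check_variant(variant)
  info <- variant_info(variant)
  if (!is.null(seed)) set.seed(seed)
  n <- n_subjects
  stopifnot(n >= 1)

  rtnorm01 <- function(n, mean, sd) {
    if (all(sd == 0)) rep(mean, n) else rtrunc_normal(n, mean, sd, 0, 1)
  }
  rlnorm_at <- function(n, value, log_sd) exp(rnorm(n, log(value), log_sd))

  hyper <- identical(group, "hyperprior")
  if (!hyper) {
    g <- utils::modifyList(default_group_parameters(variant),
                           if (is.null(group)) list() else group)
  }

  p <- tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)))
  draw_mu0 <- function(means, sd) {
    matrix(vapply(means, function(m) rnorm(n, m, sd), numeric(n)),
           nrow = n)
  }

  if (hyper) {
    mu0C <- draw_mu0(c(30, 50, 70), 100)
    mu0P <- if (info$free_mu0) draw_mu0(c(30, 50, 70), 100) else mu0C
    tau0C <- exp(rnorm(n, 1.5, 0.5))
    tau0P <- if (info$free_tau0) exp(rnorm(n, 1.5, 0.5)) else tau0C
    tau1 <- exp(rnorm(n, 1.5, 0.5))
    noise <- exp(rnorm(n, 1.5, 0.5))
    aU <- rtrunc_normal(n, 0.5, 0.3, 0, 1)
    aC <- rtrunc_normal(n, 0.5, 0.3, 0, 1)
    aP <- if (variant == "two_alpha") aC else rtrunc_normal(n, 0.5, 0.3, 0, 1)
    h <- rnorm(n, 0, 1)
    mu0U <- rnorm(n, 50, 100)
  } else {
    if (info$free_mu0) {
      mu0C <- draw_mu0(g$mu0_C, g$sigma_mu0)
      mu0P <- draw_mu0(g$mu0_P, g$sigma_mu0)
    } else {
      mu0C <- draw_mu0(g$mu0, g$sigma_mu0)
      mu0P <- mu0C
    }
    if (info$free_tau0) {
      tau0C <- rlnorm_at(n, g$tau0_C, g$log_sd)
      tau0P <- rlnorm_at(n, g$tau0_P, g$log_sd)
    } else if (info$has_tau0) {
      tau0C <- tau0P <- rlnorm_at(n, g$tau0, g$log_sd)
    } else {
      tau0C <- tau0P <- rep(NA_real_, n)
    }
    tau1 <- rlnorm_at(n, g$tau1, g$log_sd)
    noise <- rlnorm_at(n, g$noise, g$log_sd)
    aU <- rtnorm01(n, g$alpha, g$alpha_sd)
    aC <- if (variant == "two_alpha") rtnorm01(n, g$alpha_CP, g$alpha_sd)
          else if (variant == "three_alpha") rtnorm01(n, g$alpha_C, g$alpha_sd)
          else aU
    aP <- if (variant == "two_alpha") aC
          else if (variant == "three_alpha") rtnorm01(n, g$alpha_P, g$alpha_sd)
          else aU
    h <- rnorm(n, g$h, g$h_sd)
    mu0U <- if (g$mu0_U_sd == 0) rep(g$mu0_U, n)
            else rnorm(n, g$mu0_U, g$mu0_U_sd)
  }

  if (info$has_mu0) {
    p$mu0_C_30 <- mu0C[, 1]; p$mu0_C_50 <- mu0C[, 2]; p$mu0_C_70 <- mu0C[, 3]
    p$mu0_P_30 <- mu0P[, 1]; p$mu0_P_50 <- mu0P[, 2]; p$mu0_P_70 <- mu0P[, 3]
  }
  if (info$has_tau0) {
    if (info$free_tau0) {
      p$tau0_C <- tau0C; p$tau0_P <- tau0P
    } else {
      p$tau0 <- tau0C
    }
  }
  if (info$has_tau1) p$tau1 <- tau1
  if (info$has_alpha) p$alpha_U <- aU
  if (info$multi_alpha) { p$alpha_C <- aC; p$alpha_P <- aP }
  p$h <- h
  if (info$u_prior == "fixed") p$mu0_U <- mu0U
  if (info$has_noise) p$noise <- noise
  p
}

# printed reaction-time summaries of the scanner sample, used as a toy RT
# model (controllable choices are slower than colour matching)
.rt_model <- data.frame(condition = c("C", "P", "U"),
                        mean = c(1.72, 1.09, 1.02),
                        sd = c(0.66, 0.47, 0.45))

#' Simulate a full synthetic dataset from a model variant
#'
#' Builds, for each subject, six 15-trial runs (two controllable via the
#' choice model, two predictable and two unpredictable via schedule
#' matching), then draws every rating from the variant's trial-level
#' truncated normal (the same [trial_predictive_params()] used by the
#' likelihood). Reaction times follow a condition-shift toy model anchored at
#' the observed per-condition means. The generating subject parameters are
#' attached for recovery scoring and available via [true_parameters()].
#'
#' @param variant One of [model_variants()].
#' @param n_subjects Number of subjects.
#' @param group See [sample_group_parameters()].
#' @param choice_bias Softmax scale of the choice model.
#' @param match_method `"yoked"` (predictable/unpredictable runs reuse the
#'   subject's controllable sequences) or `"probability_matched"` (sampled
#'   from the choice model's per-trial frequencies).
#' @param p_timeout Probability that a rating is missing (timeout).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A trial tibble with attributes `parameters` (generating subject
#'   parameters), `group`, `variant` and `seed`.
#' @export
simulate_dataset <- function(variant = "precision_change_dynamic",
                             n_subjects = 20, group = NULL,
                             choice_bias = 0.8, match_method = "yoked",
                             p_timeout = 0, seed = NULL) {
  variant <- .check_variant(variant)
  if (!is.null(seed)) set.seed(seed)
  params <- sample_group_parameters(variant, n_subjects, group = group)

  match_freq <- NULL
  if (match_method == "probability_matched") {
    donors <- t(vapply(1:200, function(i)
      generate_controllable_sequence(choice_bias), integer(15)))
    match_freq <- t(vapply(1:15, function(t) {
      as.numeric(table(factor(donors[, t], levels = .intensity_levels))) / 200
    }, numeric(3)))
  }

  one_subject <- function(sid) {
    # each condition once per experiment half, in random order
    cond_order <- c(sample(.condition_levels), sample(.condition_levels))
    c_seqs <- list(generate_controllable_sequence(choice_bias),
                   generate_controllable_sequence(choice_bias))
    session_count <- c(C = 0L, P = 0L, U = 0L)
    runs <- lapply(1:6, function(r) {
      cond <- cond_order[r]
      session_count[cond] <<- session_count[cond] + 1L
      s <- session_count[cond]
      seq_r <- if (cond == "C") {
        c_seqs[[s]]
      } else if (match_method == "yoked") {
        c_seqs[[sample(2, 1)]]
      } else {
        generate_matched_sequence(match_freq, method = "probability_matched")
      }
      tibble::tibble(subject_id = sid, session = as.integer(s),
                     run = as.integer(r), trial = 1:15,
                     condition = cond, intensity_level = as.numeric(seq_r))
    })
    dplyr::bind_rows(runs)
  }

  trials <- dplyr::bind_rows(lapply(params$subject_id, one_subject))
  trials <- trial_predictive_params(variant, params, trials)
  ntr <- nrow(trials)
  trials$rating <- rtrunc_normal(ntr, trials$pred_mu, trials$pred_sd)
  if (p_timeout > 0) {
    trials$rating[runif(ntr) < p_timeout] <- NA_real_
  }
  rt_row <- match(trials$condition, .rt_model$condition)
  trials$reaction_time <- rtrunc_normal(ntr, .rt_model$mean[rt_row],
                                        .rt_model$sd[rt_row],
                                        lo = 0.1, hi = 8)
  trials$chosen <- trials$condition == "C"
  trials <- trials[intersect(c(trial_columns(), "w_30", "w_50", "w_70"),
                             names(trials))]
  attr(trials, "parameters") <- params
  attr(trials, "variant") <- variant
  attr(trials, "seed") <- seed
  class(trials) <- c("pain_sim", class(trials))
  trials
}

#' Generating parameters of a simulated dataset
#'
#' @param data A dataset from [simulate_dataset()].
#' @return The subject-parameter tibble that generated the ratings.
#' @export
true_parameters <- function(data) {
  p <- attr(data, "parameters")
  if (is.null(p)) {
    stop("`data` carries no generating parameters.", call. = FALSE)
  }
  p
}

#' Simulate rating data with a controlled condition-by-intensity interaction
#'
#' A linear-mixed-model generator for calibration and power studies: ratings
#' are truncated-normal draws around a linear predictor with a subject
#' random intercept, a linear intensity slope anchored at VAS 0, and
#' condition effects scaled by the controllable-vs-unpredictable interaction
#' `effect` (the predictable condition gets 0.69 of it, the observed ratio).
#' `effect = 0` removes all condition differences.
#'
#' @param n_subjects Number of subjects.
#' @param effect Slope increase (VAS rating per VAS intensity unit) of the
#'   controllable relative to the unpredictable condition.
#' @param subject_sd SD of the subject random intercepts.
#' @param resid_sd Residual SD of the ratings.
#' @param seed Optional integer seed.
#' @return A trial tibble.
#' @export
simulate_lmm_dataset <- function(n_subjects = 20, effect = 0.29,
                                 subject_sd = 8, resid_sd = 12,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    run = 1:6, trial = 1:15)
  cond_of_run <- function() c(sample(.condition_levels),
                              sample(.condition_levels))
  conds <- vapply(seq_len(n_subjects), function(i) cond_of_run(),
                  character(6))
  grid$condition <- conds[cbind(grid$run,
                                match(grid$subject_id,
                                      unique(grid$subject_id)))]
  grid <- grid |>
    dplyr::group_by(.data$subject_id, .data$run) |>
    dplyr::mutate(intensity_level = sample(rep(.intensity_levels, 5))) |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::mutate(session = as.integer(factor(.data$run,
                                              levels = unique(.data$run)))) |>
    dplyr::ungroup()
  u <- rnorm(n_subjects, 0, subject_sd)
  names(u) <- unique(grid$subject_id)
  e_cu <- effect
  e_pu <- 0.69 * effect
  mu <- -16.8 + 1.177 * grid$intensity_level + u[grid$subject_id] +
    (grid$condition == "C") * (-63.1 * e_cu + e_cu * grid$intensity_level) +
    (grid$condition == "P") * (-61.0 * e_pu + e_pu * grid$intensity_level)
  grid$rating <- rtrunc_normal(nrow(grid), mu, resid_sd)
  rt_row <- match(grid$condition, .rt_model$condition)
  grid$reaction_time <- rtrunc_normal(nrow(grid), .rt_model$mean[rt_row],
                                      .rt_model$sd[rt_row], lo = 0.1, hi = 8)
  grid$chosen <- grid$condition == "C"
  grid[trial_columns()]
}

#' Simulation-based power analysis for the rating mixed model
#'
#' For each sample size, simulates `reps` datasets with a given
#' controllable-vs-unpredictable interaction, fits the Bayesian rating mixed
#' model, and records the fraction of replicates whose 95% HPDI for that
#' interaction excludes zero.
#'
#' @param n_grid Integer vector of sample sizes.
#' @param effect Interaction magnitude (see [simulate_lmm_dataset()]).
#' @param reps Replicates per sample size.
#' @param seed Integer seed.
#' @param mcmc MCMC profile for the mixed-model fits (default `"smoke"`;
#'   power estimates need many fits, not long chains).
#' @return Tibble with `n`, `power`, `reps`.
#' @export
simulate_power <- function(n_grid, effect = 0.29, reps = 20, seed = 1,
                           mcmc = "smoke") {
  stopifnot(reps >= 1)
  res <- purrr::map_dfr(n_grid, function(n) {
    hits <- vapply(seq_len(reps), function(r) {
      rs <- seed + 1000L * r + n
      d <- simulate_lmm_dataset(n, effect = effect, seed = rs)
      fit <- fit_rating_lmm(d, baseline = "U", mcmc = mcmc, seed = rs,
                            both_baselines = FALSE)
      row <- fit$coefficients[fit$coefficients$term ==
                                "intensity_level:conditionC", ]
      row$hpdi_lo > 0 | row$hpdi_hi < 0
    }, logical(1))
    tibble::tibble(n = n, power = mean(hits), reps = reps)
  })
  res
}
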