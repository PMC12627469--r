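# The eight generative model variants of the rating task, their subject-level
# parameter sets, and the trial-level predictive distribution shared between
# the synthetic-data generator and the likelihood (one code path for both).

#' Model variants
#'
#' The eight generative accounts of the rating data that the package can
#' simulate, fit, and compare:
#'
#' * `null_hab`: ratings are noisy readouts of the habituation-adjusted VAS
#'   target in every condition.
#' * `null_means`: controllable/predictable ratings are drawn from free
#'   per-condition prior means (shared dispersion), unpredictable ratings are
#'   noisy readouts of the target -- no expectation bias in U.
#' * `mean_shift_fixed` / `mean_shift_dynamic`: expectation-integration model
#'   in which the controllable and predictable conditions get separate prior
#'   means but share one prior SD; the unpredictable prior mean is either a
#'   subject-constant free parameter (fixed) or tracks the remaining stimulus
#'   counts (dynamic).
#' * `precision_change_fixed` / `precision_change_dynamic`: prior means are
#'   shared between the controllable and predictable conditions but each
#'   condition has its own prior SD -- control changes expectation precision,
#'   not content.
#' * `two_alpha` / `three_alpha`: every condition's rating arises from
#'   shrinking the prior mean towards the (habituation-adjusted) target with
#'   a condition-specific likelihood weight (one shared weight for C and P in
#'   `two_alpha`; three separate weights in `three_alpha`), with a dynamic
#'   unpredictable prior.
#'
#' @return Character vector of variant names.
#' @export
model_variants <- function() {
  c("null_hab", "null_means",
    "mean_shift_fixed", "mean_shift_dynamic",
    "precision_change_fixed", "precision_change_dynamic",
    "two_alpha", "three_alpha")
}

.check_variant <- function(variant) {
  variant <- match.arg(variant, model_variants())
  variant
}

# structural description of a variant, used by the generator, the likelihood,
# the JAGS code builder and the recovery report
variant_info <- function(variant) {
  variant <- .check_variant(variant)
  info <- list(
    variant = variant,
    # do C/P trials sample straight from the prior (vs shrink towards y_t)?
    sample_from_prior = !variant %in% c("null_hab", "two_alpha",
                                        "three_alpha"),
    has_mu0   = variant != "null_hab",
    free_mu0  = variant %in% c("null_means", "mean_shift_fixed",
                               "mean_shift_dynamic"),
    free_tau0 = variant %in% c("precision_change_fixed",
                               "precision_change_dynamic"),
    has_tau0  = variant %in% c("null_means", "mean_shift_fixed",
                               "mean_shift_dynamic", "precision_change_fixed",
                               "precision_change_dynamic"),
    has_tau1  = !variant %in% c("null_hab", "null_means"),
    has_noise = variant %in% c("null_hab", "null_means"),
    has_alpha = !variant %in% c("null_hab", "null_means"),
    multi_alpha = variant %in% c("two_alpha", "three_alpha"),
    u_prior = if (variant %in% c("mean_shift_fixed", "precision_change_fixed"))
      "fixed"
    else if (variant %in% c("null_hab", "null_means")) "none"
    else "dynamic"
  )
  info$free_params <- c(
    if (info$has_mu0 && !info$free_mu0) paste0("mu0_", c(30, 50, 70)),
    if (info$free_mu0) c(paste0("mu0_C_", c(30, 50, 70)),
                         paste0("mu0_P_", c(30, 50, 70))),
    if (info$has_tau0 && !info$free_tau0) "tau0",
    if (info$free_tau0) c("tau0_C", "tau0_P"),
    if (info$has_tau1) "tau1",
    if (info$has_alpha) "alpha_U",
    if (variant == "two_alpha") "alpha_CP",
    if (variant == "three_alpha") c("alpha_C", "alpha_P"),
    if (info$u_prior == "fixed") "mu0_U",
    "h",
    if (info$has_noise) "noise"
  )
  info
}

#' MCMC settings profiles
#'
#' `paper`: 4 chains, 4000 iterations of which 1000 warm-up -- the settings
#' used for the main fits. `recovery`: 4 chains, 1000 iterations / 500
#' warm-up -- the reduced settings for simulate-and-refit studies. `smoke`: a
#' minimal profile for fast end-to-end checks.
#'
#' @param profile One of `"paper"`, `"recovery"`, `"smoke"`, or a list with
#'   elements `chains`, `iter`, `warmup` (and optionally `adapt`, `thin`).
#' @return List with `chains`, `iter` (total, including warm-up), `warmup`,
#'   `adapt`, `thin`.
#' @export
mcmc_profile <- function(profile = "paper") {
  if (is.list(profile)) {
    out <- utils::modifyList(
      list(chains = 4L, iter = 4000L, warmup = 1000L, adapt = 500L,
           thin = 1L),
      profile)
    return(out)
  }
  switch(match.arg(profile, c("paper", "recovery", "smoke")),
    paper    = list(chains = 4L, iter = 4000L, warmup = 1000L, adapt = 500L,
                    thin = 1L),
    recovery = list(chains = 4L, iter = 1000L, warmup = 500L, adapt = 300L,
                    thin = 1L),
    smoke    = list(chains = 2L, iter = 400L, warmup = 200L, adapt = 150L,
                    thin = 1L))
}

#' Specify a model variant with its hyperpriors and MCMC settings
#'
#' The hyperpriors follow the hierarchical scheme of the observer models:
#' per-level prior means are partially pooled across subjects around group
#' means with pooling SD `sigma_mu0`; SD-type parameters get log-normal
#' priors; the likelihood weight `alpha` gets a `[0,1]`-truncated normal;
#' the habituation slope a standard normal. All values are in VAS units.
#'
#' @param variant One of [model_variants()].
#' @param mcmc An [mcmc_profile()] name or list.
#' @param hyper Optional named list overriding individual hyperprior values
#'   (see the default list in the function body).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(variant, mcmc = "paper", hyper = list()) {
  variant <- .check_variant(variant)
  defaults <- list(
    mu0_mean = c(30, 50, 70),   # group-mean priors per level
    mu0_sd = 100,
    log_sigma_mu0 = c(1.5, 0.5),
    log_tau0 = c(1.5, 0.5),
    log_tau1 = c(1.5, 0.5),
    log_noise = c(1.5, 0.5),
    alpha = c(0.5, 0.3),        # truncated to [0, 1]
    h = c(0, 1),
    mu0_U = c(50, 100)          # fixed unpredictable prior mean
  )
  structure(
    list(variant = variant,
         info = variant_info(variant),
         hyper = utils::modifyList(defaults, hyper),
         mcmc = mcmc_profile(mcmc)),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$variant, "\n",
      "  mcmc: ", x$mcmc$chains, " chains, ", x$mcmc$iter, " iterations (",
      x$mcmc$warmup, " warm-up)\n", sep = "")
  cat("  free parameters:", paste(x$info$free_params, collapse = ", "), "\n")
  invisible(x)
}

#' Dynamic-prior weights and habituation-adjusted targets per trial
#'
#' Adds to a trial table the remaining-count weights `w_30`, `w_50`, `w_70`
#' that define the dynamic unpredictable prior (remaining occurrences of each
#' level divided by remaining trials, computed from the applied sequence of
#' the trial's run) and is the common preprocessing step of the generator and
#' the likelihood.
#'
#' @param trials Trial tibble (needs `subject_id`, `run`, `trial`,
#'   `intensity_level`).
#' @return `trials` with columns `w_30`, `w_50`, `w_70` appended.
#' @export
add_dynamic_weights <- function(trials) {
  trials |>
    dplyr::group_by(.data$subject_id, .data$run) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(
      w_30 = (5 - cumsum(.data$intensity_level == 30) +
                (.data$intensity_level == 30)) / (16 - .data$trial),
      w_50 = (5 - cumsum(.data$intensity_level == 50) +
                (.data$intensity_level == 50)) / (16 - .data$trial),
      w_70 = (5 - cumsum(.data$intensity_level == 70) +
                (.data$intensity_level == 70)) / (16 - .data$trial)) |>
    dplyr::ungroup()
}

# Precompute the trial-indexed structures the predictive core needs:
# subject/level indices, condition masks, habituation inputs, dynamic
# weights. Shared by the generator, the likelihood and the per-draw
# log-likelihood matrix.
.trial_precomp <- function(trials, variant) {
  info <- variant_info(variant)
  if (info$u_prior == "dynamic" && !all(c("w_30", "w_50", "w_70") %in%
                                        names(trials))) {
    trials <- add_dynamic_weights(trials)
  }
  subjects <- unique(trials$subject_id)
  list(
    trials = trials,
    subjects = subjects,
    s = match(trials$subject_id, subjects),
    lev = match(trials$intensity_level, .intensity_levels),
    isC = trials$condition == "C",
    isP = trials$condition == "P",
    isU = trials$condition == "U",
    t = trials$trial,
    y = trials$intensity_level,
    w = if (info$u_prior == "dynamic")
      cbind(trials$w_30, trials$w_50, trials$w_70) else NULL
  )
}

# The single predictive core: given per-subject parameter arrays (matrices
# mu0_C / mu0_P of dim S x 3; vectors tau0, tau0_C, tau0_P, tau1, alpha_U,
# alpha_C, alpha_P, h, mu0_U, noise) and a .trial_precomp() list, return the
# trial-level truncated-normal mean and SD. Both simulation and likelihood
# evaluation go through here.
.pred_core <- function(variant, P, pre) {
  info <- variant_info(variant)
  s <- pre$s
  y_t <- habituated_mean(pre$y, P$h[s], pre$t)
  if (variant == "null_hab") {
    return(list(mu = y_t, sd = P$noise[s]))
  }
  idx <- cbind(s, pre$lev)
  mu0C_lev <- P$mu0_C[idx]
  mu0P_lev <- P$mu0_P[idx]
  mu0_cond <- ifelse(pre$isP, mu0P_lev, mu0C_lev)
  m0u <- switch(info$u_prior,
    dynamic = {
      bar <- (P$mu0_C + P$mu0_P) / 2
      pre$w[, 1] * bar[s, 1] + pre$w[, 2] * bar[s, 2] + pre$w[, 3] * bar[s, 3]
    },
    fixed = P$mu0_U[s],
    none = rep(NA_real_, length(s)))

  if (info$multi_alpha) {
    a <- ifelse(pre$isU, P$alpha_U[s],
                ifelse(pre$isP, P$alpha_P[s], P$alpha_C[s]))
    prior <- ifelse(pre$isU, m0u, mu0_cond)
    list(mu = prior + a * (y_t - prior), sd = P$tau1[s])
  } else if (variant == "null_means") {
    list(mu = ifelse(pre$isU, y_t, mu0_cond - P$h[s] * pre$t),
         sd = ifelse(pre$isU, P$noise[s], P$tau0[s]))
  } else {
    sd_cp <- if (info$free_tau0) {
      ifelse(pre$isC, P$tau0_C[s], P$tau0_P[s])
    } else {
      P$tau0[s]
    }
    list(mu = ifelse(pre$isU, m0u + P$alpha_U[s] * (y_t - m0u),
                     mu0_cond - P$h[s] * pre$t),
         sd = ifelse(pre$isU, P$tau1[s], sd_cp))
  }
}

# subject-parameter tibble -> the array form .pred_core() consumes
.params_arrays <- function(params, subjects) {
  ord <- match(subjects, params$subject_id)
  if (anyNA(ord)) {
    stop("`params` lacks rows for some subjects in `trials`.", call. = FALSE)
  }
  p <- params[ord, ]
  grab <- function(nm) if (nm %in% names(p)) p[[nm]] else NULL
  mu0m <- function(prefix) {
    if (!paste0(prefix, "_30") %in% names(p)) return(NULL)
    cbind(p[[paste0(prefix, "_30")]], p[[paste0(prefix, "_50")]],
          p[[paste0(prefix, "_70")]])
  }
  list(mu0_C = mu0m("mu0_C"), mu0_P = mu0m("mu0_P"),
       tau0 = grab("tau0"), tau0_C = grab("tau0_C"),
       tau0_P = grab("tau0_P"), tau1 = grab("tau1"),
       alpha_U = grab("alpha_U"), alpha_C = grab("alpha_C"),
       alpha_P = grab("alpha_P"), h = grab("h"),
       mu0_U = grab("mu0_U"), noise = grab("noise"))
}

#' Trial-level predictive distribution
#'
#' For every trial, the mean and SD of the truncated normal from which the
#' variant says the rating is drawn. This single function backs both the
#' synthetic-data generator (which samples from it) and the likelihood (which
#' evaluates rating densities under it), so simulation and inference cannot
#' drift apart.
#'
#' @param variant A variant name or a [model_spec()].
#' @param params Subject-parameter tibble (one row per subject, columns as
#'   produced by [sample_group_parameters()]).
#' @param trials Trial tibble; dynamic weights are computed on the fly if the
#'   `w_*` columns are absent.
#' @return `trials` with columns `pred_mu` and `pred_sd` appended (and the
#'   dynamic-weight columns, when the variant uses them).
#' @export
trial_predictive_params <- function(variant, params, trials) {
  if (inherits(variant, "model_spec")) variant <- variant$variant
  variant <- .check_variant(variant)
  pre <- .trial_precomp(trials, variant)
  P <- .params_arrays(params, pre$subjects)
  ms <- .pred_core(variant, P, pre)
  out <- pre$trials
  out$pred_mu <- ms$mu
  out$pred_sd <- ms$sd
  out
}

#' Pointwise log-likelihood of observed ratings
#'
#' Log density of each non-missing rating under the variant's trial-level
#' truncated normal on `[0, 100]`. Rows with missing ratings (timeouts) are
#' dropped, matching the fitting path.
#'
#' @inheritParams trial_predictive_params
#' @return Tibble of the scored trials with a `loglik` column.
#' @export
log_likelihood <- function(variant, params, trials) {
  scored <- trial_predictive_params(variant, params, trials)
  scored <- scored[!is.na(scored$rating), ]
  if (any(scored$rating < 0 | scored$rating > 100)) {
    stop("Ratings outside [0, 100] cannot be scored.", call. = FALSE)
  }
  scored$loglik <- dtrunc_normal(scored$rating, scored$pred_mu,
                                 scored$pred_sd, log = TRUE)
  scored
}
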