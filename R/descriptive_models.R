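# Bayesian regressions of the behavioural read-outs: the condition-by-
# intensity mixed model on ratings, the mixed model on within-subject rating
# SDs, linear/quadratic choice-frequency models, and the within-subject SEM
# correction for condition plots.

# generic Bayesian linear model in JAGS: y ~ X beta (+ subject intercept)
# priors: "weak" = N(0,50) intercept, Cauchy(0, 2.5) slopes, uniform
# positive error SD; "flat" = N(0, 1e4) on every coefficient (numerically
# flat at the scale of the data)
.jags_lm <- function(y, X, subject = NULL, priors = c("weak", "flat"),
                     mcmc = "paper", seed = 1, quiet = TRUE) {
  priors <- match.arg(priors)
  mc <- mcmc_profile(mcmc)
  K <- ncol(X)
  has_ranef <- !is.null(subject)
  beta_prior <- if (priors == "flat") {
    "beta[k] ~ dnorm(0, 1.0E-8)"
  } else {
    paste0("beta[k] ~ dt(0, 0.16, 1)") # Cauchy(0, 2.5): 1/2.5^2 = 0.16
  }
  code <- paste0(
    "model {\n",
    if (priors == "weak") "  beta[1] ~ dnorm(0, 4.0E-4)\n" else
      "  beta[1] ~ dnorm(0, 1.0E-8)\n",
    "  for (k in 2:K) { ", beta_prior, " }\n",
    "  sigma ~ dunif(0, 1000)\n",
    if (has_ranef) paste0(
      "  sigu ~ dunif(0, 1000)\n",
      "  for (s in 1:S) { u[s] ~ dnorm(0, pow(sigu, -2)) }\n"),
    "  for (i in 1:N) {\n",
    "    y[i] ~ dnorm(inprod(X[i, ], beta)",
    if (has_ranef) " + u[subj[i]]", ", pow(sigma, -2))\n",
    "  }\n}\n")
  data <- list(y = y, X = X, N = length(y), K = K)
  if (has_ranef) {
    subjects <- unique(subject)
    data$subj <- match(subject, subjects)
    data$S <- length(subjects)
  }
  model <- rjags::jags.model(textConnection(code), data = data,
                             inits = .chain_inits(seed, mc$chains),
                             n.chains = mc$chains, n.adapt = mc$adapt,
                             quiet = quiet)
  stats::update(model, mc$warmup, progress.bar = "none")
  monitors <- c("beta", "sigma", if (has_ranef) "sigu")
  draws <- rjags::coda.samples(model, monitors,
                               n.iter = mc$iter - mc$warmup, thin = mc$thin,
                               progress.bar = "none")
  bdraws <- do.call(rbind, lapply(draws, function(m) {
    as.matrix(m)[, sprintf("beta[%d]", seq_len(K)), drop = FALSE]
  }))
  colnames(bdraws) <- colnames(X)
  diag <- mcmc_diagnostics(draws)
  list(beta_draws = bdraws, draws = draws, diagnostics = diag,
       converged = all(diag$rhat < 1.01, na.rm = TRUE))
}

.coef_table <- function(beta_draws, diagnostics = NULL, mass = 0.95) {
  terms <- colnames(beta_draws)
  out <- purrr::map_dfr(seq_along(terms), function(k) {
    hp <- hpdi(beta_draws[, k], mass)
    tibble::tibble(term = terms[k], mean = mean(beta_draws[, k]),
                   hpdi_lo = hp[["lo"]], hpdi_hi = hp[["hi"]])
  })
  if (!is.null(diagnostics)) {
    dmap <- diagnostics[match(sprintf("beta[%d]", seq_along(terms)),
                              diagnostics$parameter), ]
    out$rhat <- dmap$rhat
    out$ess <- dmap$ess
  }
  out
}

#' Bayesian mixed model of pain ratings
#'
#' Linear mixed model with intensity as a linear covariate anchored at the
#' pain threshold (VAS 0), condition dummies, condition-by-intensity
#' interactions, trial and session number as fixed effects, and a subject
#' random intercept. Priors: `N(0, 50)` on the intercept, `Cauchy(0, 2.5)`
#' on predictor weights, uniform positive error SD. To report all pairwise
#' condition contrasts, the model is refit with a second baseline and the
#' interaction posteriors are assembled from both parameterisations
#' (`C_vs_U` is the slope increase from the unpredictable to the
#' controllable condition, and so on).
#'
#' @param trials Trial tibble (missing ratings dropped).
#' @param baseline Condition used as reference in the primary fit.
#' @param mcmc MCMC profile.
#' @param seed Integer seed.
#' @param both_baselines Also fit the complementary baseline and assemble
#'   pairwise interaction contrasts (default `TRUE`).
#' @return A `pain_lmm`: `coefficients` (primary baseline), `pairwise`
#'   (condition-pair interaction summaries, when requested), convergence
#'   diagnostics, and the posterior draws of the fixed effects.
#' @export
fit_rating_lmm <- function(trials, baseline = "C", mcmc = "paper", seed = 1,
                           both_baselines = TRUE) {
  baseline <- match.arg(baseline, .condition_levels)
  d <- dplyr::filter(tibble::as_tibble(trials), !is.na(.data$rating))
  if (dplyr::n_distinct(d$condition) < 2) {
    stop("Need at least two conditions.", call. = FALSE)
  }
  build_X <- function(base) {
    d2 <- d
    d2$condition <- stats::relevel(factor(d2$condition,
                                          levels = .condition_levels), base)
    model.matrix(~ intensity_level + condition +
                   condition:intensity_level + trial + session, d2)
  }
  fit1 <- .jags_lm(d$rating, build_X(baseline), subject = d$subject_id,
                   priors = "weak", mcmc = mcmc, seed = seed)
  out <- list(outcome = "rating", baseline = baseline,
              coefficients = .coef_table(fit1$beta_draws, fit1$diagnostics),
              beta_draws = fit1$beta_draws,
              diagnostics = fit1$diagnostics, converged = fit1$converged)
  if (both_baselines) {
    base2 <- setdiff(.condition_levels, baseline)[1]
    fit2 <- .jags_lm(d$rating, build_X(base2), subject = d$subject_id,
                     priors = "weak", mcmc = mcmc, seed = seed + 1)
    out$baseline2 <- base2
    out$coefficients2 <- .coef_table(fit2$beta_draws, fit2$diagnostics)
    out$converged <- out$converged && fit2$converged
    # assemble the three pairwise interaction contrasts, oriented as the
    # slope increase from the second-named to the first-named condition
    pair_draw <- function(hi, lo) {
      pick <- function(fit, base, cond) {
        nm <- sprintf("intensity_level:condition%s", cond)
        if (base == cond || !nm %in% colnames(fit$beta_draws)) NULL
        else fit$beta_draws[, nm]
      }
      # interaction term condX:intensity in a fit with baseline B is
      # slope(X) - slope(B)
      v <- pick(fit1, baseline, hi)
      b <- baseline
      if (is.null(v)) { v <- pick(fit2, base2, hi); b <- base2 }
      if (!is.null(v) && b == lo) return(v)
      v2 <- pick(fit1, baseline, lo)
      b2 <- baseline
      if (is.null(v2)) { v2 <- pick(fit2, base2, lo); b2 <- base2 }
      if (!is.null(v2) && b2 == hi) return(-v2)
      if (!is.null(v) && !is.null(v2) && b == b2) return(v - v2)
      stop("Cannot assemble contrast ", hi, " vs ", lo, call. = FALSE)
    }
    pairs <- list(c("C", "U"), c("P", "U"), c("C", "P"))
    out$pairwise <- purrr::map_dfr(pairs, function(pr) {
      dr <- pair_draw(pr[1], pr[2])
      hp <- hpdi(dr)
      tibble::tibble(term = sprintf("interaction_%s_vs_%s", pr[1], pr[2]),
                     mean = mean(dr), hpdi_lo = hp[["lo"]],
                     hpdi_hi = hp[["hi"]])
    })
  }
  class(out) <- "pain_lmm"
  out
}

#' Bayesian mixed model of within-subject rating variability
#'
#' Mixed model on the subject-by-condition-by-intensity standard deviations
#' from [within_subject_sd_table()], with condition and intensity both as
#' factors (the intensity effect on variability is inverted-U-shaped, so a
#' linear term would misrepresent it) and a subject random intercept. Fit
#' with two baseline settings -- unpredictable/low and controllable/medium --
#' and assembled into all pairwise condition and intensity contrasts.
#'
#' @param sd_table Output of [within_subject_sd_table()].
#' @param mcmc MCMC profile.
#' @param seed Integer seed.
#' @return A `pain_lmm` with `coefficients` (first parameterisation) and
#'   `pairwise` contrasts (`P_vs_U` is the SD change from unpredictable to
#'   predictable, `med_vs_low` from low to medium intensity, ...).
#' @export
fit_sd_lmm <- function(sd_table, mcmc = "paper", seed = 1) {
  d <- dplyr::filter(tibble::as_tibble(sd_table), !is.na(.data$sd))
  build_X <- function(cond_base, int_base) {
    d2 <- d
    d2$condition <- stats::relevel(factor(d2$condition,
                                          levels = .condition_levels),
                                   cond_base)
    d2$intensity <- stats::relevel(
      factor(d2$intensity_level, levels = .intensity_levels,
             labels = c("low", "med", "high")), int_base)
    model.matrix(~ condition + intensity, d2)
  }
  fit1 <- .jags_lm(d$sd, build_X("U", "low"), subject = d$subject_id,
                   priors = "weak", mcmc = mcmc, seed = seed)
  fit2 <- .jags_lm(d$sd, build_X("C", "med"), subject = d$subject_id,
                   priors = "weak", mcmc = mcmc, seed = seed + 1)
  grab <- function(fit, nm, flip = FALSE) {
    dr <- fit$beta_draws[, nm]
    if (flip) dr <- -dr
    hp <- hpdi(dr)
    tibble::tibble(mean = mean(dr), hpdi_lo = hp[["lo"]],
                   hpdi_hi = hp[["hi"]])
  }
  pairwise <- dplyr::bind_rows(
    dplyr::mutate(grab(fit1, "conditionP"), term = "P_vs_U", .before = 1),
    dplyr::mutate(grab(fit1, "conditionC"), term = "C_vs_U", .before = 1),
    dplyr::mutate(grab(fit2, "conditionP"), term = "P_vs_C", .before = 1),
    dplyr::mutate(grab(fit1, "intensitymed"), term = "med_vs_low",
                  .before = 1),
    dplyr::mutate(grab(fit1, "intensityhigh"), term = "high_vs_low",
                  .before = 1),
    dplyr::mutate(grab(fit2, "intensityhigh"), term = "high_vs_med",
                  .before = 1))
  structure(
    list(outcome = "sd", baseline = "U/low",
         coefficients = .coef_table(fit1$beta_draws, fit1$diagnostics),
         coefficients2 = .coef_table(fit2$beta_draws, fit2$diagnostics),
         pairwise = pairwise, beta_draws = fit1$beta_draws,
         diagnostics = fit1$diagnostics,
         converged = fit1$converged && fit2$converged),
    class = "pain_lmm")
}

#' @export
print.pain_lmm <- function(x, ...) {
  cat("<pain_lmm> outcome:", x$outcome, " baseline:", x$baseline,
      " converged:", x$converged, "\n")
  print(x$coefficients)
  if (!is.null(x$pairwise)) {
    cat("pairwise contrasts:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Bayesian choice-frequency regression over trial positions
#'
#' Regresses the group-level percentage of choices of one intensity level on
#' the within-run trial position (degree 1) or on trial position and its
#' square (degree 2), with flat priors -- one observation per position. The
#' model ELPD (PSIS leave-one-out) is returned so linear and quadratic fits
#' can be compared; the medium level's inverted-U choice pattern favours the
#' quadratic model.
#'
#' @param choice_table Output of [choice_percentages()].
#' @param level Intensity level to model (30, 50 or 70).
#' @param degree 1 (linear) or 2 (adds a quadratic term).
#' @param mcmc MCMC profile.
#' @param seed Integer seed.
#' @return A `pain_choice_fit`: coefficient summaries, the fixed-effect
#'   draws, and an `elpd` result.
#' @export
fit_choice_freq <- function(choice_table, level, degree = 1, mcmc = "paper",
                            seed = 1) {
  stopifnot(degree %in% 1:2)
  d <- dplyr::filter(tibble::as_tibble(choice_table),
                     .data$intensity_level == level)
  if (nrow(d) != 15) {
    stop("Expected one percentage per trial position 1..15.", call. = FALSE)
  }
  d <- dplyr::arrange(d, .data$trial)
  X <- if (degree == 1) {
    model.matrix(~ trial, d)
  } else {
    model.matrix(~ trial + I(trial^2), d)
  }
  fit <- .jags_lm(d$percent, X, subject = NULL, priors = "flat",
                  mcmc = mcmc, seed = seed)
  # pointwise log-likelihood over the posterior for LOO model comparison
  sig <- do.call(rbind, lapply(fit$draws, as.matrix))[, "sigma"]
  mu <- fit$beta_draws %*% t(X)
  ll <- dnorm(matrix(d$percent, nrow(mu), ncol(mu), byrow = TRUE), mu,
              matrix(sig, nrow(mu), ncol(mu)), log = TRUE)
  structure(
    list(level = level, degree = degree,
         coefficients = .coef_table(fit$beta_draws, fit$diagnostics),
         beta_draws = fit$beta_draws,
         elpd = psis_loo(ll), converged = fit$converged),
    class = "pain_choice_fit")
}

#' @export
print.pain_choice_fit <- function(x, ...) {
  cat("<pain_choice_fit> level:", x$level, " degree:", x$degree,
      " elpd:", round(x$elpd$elpd, 2), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Within-subject corrected standard error of the mean
#'
#' For repeated-measures condition plots, the naive SEM mixes
#' between-subject offsets into the error bars. This correction removes each
#' subject's mean (adding back the grand mean) before computing cell SEMs,
#' and multiplies by the small-sample factor `sqrt(M / (M - 1))` for `M`
#' cells. Subjects with incomplete cell grids are excluded with a warning.
#'
#' @param data A tibble of per-subject cell means.
#' @param value Column with the cell means (tidy-eval).
#' @param subject Column identifying subjects (tidy-eval).
#' @param ... Grouping columns defining the cells (tidy-eval).
#' @return Tibble with the cell identifiers, `mean`, `sem` (corrected), and
#'   `n` subjects.
#' @export
within_subject_sem <- function(data, value, subject, ...) {
  value <- rlang::enquo(value)
  subject <- rlang::enquo(subject)
  cells <- rlang::enquos(...)
  d <- dplyr::transmute(tibble::as_tibble(data),
                        .subject = !!subject, !!!cells,
                        .value = !!value)
  cell_cols <- setdiff(names(d), c(".subject", ".value"))
  # collapse repeated observations to one cell mean per subject
  d <- d |>
    dplyr::group_by(.data$.subject, !!!rlang::syms(cell_cols)) |>
    dplyr::summarise(.value = mean(.data$.value), .groups = "drop")
  n_cells <- nrow(dplyr::distinct(d[cell_cols]))
  complete <- d |>
    dplyr::group_by(.data$.subject) |>
    dplyr::summarise(ok = dplyr::n() == n_cells &&
                       !anyNA(.data$.value), .groups = "drop")
  if (any(!complete$ok)) {
    warning("Excluding subject(s) with incomplete cells: ",
            paste(complete$.subject[!complete$ok], collapse = ", "),
            call. = FALSE)
    d <- d[d$.subject %in% complete$.subject[complete$ok], ]
  }
  grand <- mean(d$.value)
  if (n_cells > 1) {
    d <- d |>
      dplyr::group_by(.data$.subject) |>
      dplyr::mutate(.centered = .data$.value - mean(.data$.value) + grand) |>
      dplyr::ungroup()
  } else {
    d$.centered <- d$.value # single cell: no within-subject structure
  }
  corr <- if (n_cells > 1) sqrt(n_cells / (n_cells - 1)) else 1
  d |>
    dplyr::group_by(!!!rlang::syms(cell_cols)) |>
    dplyr::summarise(mean = mean(.data$.value),
                     sem = corr * stats::sd(.data$.centered) /
                       sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}
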