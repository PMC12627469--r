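# Hierarchical MCMC fitting of the observer-model variants via JAGS:
# model-code generation, seeded sampling, convergence diagnostics
# (split-R-hat, effective sample size), HPDI, pointwise log-likelihood
# matrices, posterior prediction, and parameter recovery.

# JAGS model code for a variant. Subject-level prior means are partially
# pooled around per-level group means; SD-type parameters live on the log
# scale; likelihood weights are [0,1]-truncated. The per-trial mean/SD
# structure mirrors .pred_core() exactly (asserted by a test that compares
# monitored mu/sd nodes against the R core).
jags_code <- function(spec) {
  info <- spec$info
  hy <- spec$hyper
  prec <- function(sd) formatC(1 / sd^2, format = "g", digits = 12)
  lp <- function(ms) sprintf("dnorm(%g, %s)", ms[1], prec(ms[2]))

  blocks <- character()
  if (info$has_mu0) {
    blocks <- c(blocks, sprintf(
      "for (l in 1:3) { gm[l] ~ dnorm(gm_mean[l], %s) }", prec(hy$mu0_sd)),
      sprintf("lsig_mu0 ~ %s", lp(hy$log_sigma_mu0)),
      "sigma_mu0 <- exp(lsig_mu0)",
      "prec_mu0 <- pow(sigma_mu0, -2)")
  }

  sub <- character()
  if (info$has_mu0) {
    sub <- c(sub, "for (l in 1:3) { mu0C[s, l] ~ dnorm(gm[l], prec_mu0) }")
    if (info$free_mu0) {
      sub <- c(sub, "for (l in 1:3) { mu0P[s, l] ~ dnorm(gm[l], prec_mu0) }")
    }
  }
  if (info$has_tau0) {
    if (info$free_tau0) {
      sub <- c(sub,
        sprintf("lt0C[s] ~ %s", lp(hy$log_tau0)), "tau0C[s] <- exp(lt0C[s])",
        sprintf("lt0P[s] ~ %s", lp(hy$log_tau0)), "tau0P[s] <- exp(lt0P[s])")
    } else {
      sub <- c(sub,
        sprintf("lt0[s] ~ %s", lp(hy$log_tau0)), "tau0[s] <- exp(lt0[s])")
    }
  }
  if (info$has_tau1) {
    sub <- c(sub,
      sprintf("lt1[s] ~ %s", lp(hy$log_tau1)), "tau1[s] <- exp(lt1[s])")
  }
  if (info$has_noise) {
    sub <- c(sub,
      sprintf("lno[s] ~ %s", lp(hy$log_noise)), "noise[s] <- exp(lno[s])")
  }
  ab <- sprintf("%s T(0, 1)", lp(hy$alpha))
  if (info$has_alpha) sub <- c(sub, sprintf("alphaU[s] ~ %s", ab))
  if (spec$variant == "two_alpha") {
    sub <- c(sub, sprintf("alphaC[s] ~ %s", ab), "alphaP[s] <- alphaC[s]")
  }
  if (spec$variant == "three_alpha") {
    sub <- c(sub, sprintf("alphaC[s] ~ %s", ab),
             sprintf("alphaP[s] ~ %s", ab))
  }
  sub <- c(sub, sprintf("h[s] ~ %s", lp(hy$h)))
  if (info$u_prior == "fixed") {
    sub <- c(sub, sprintf("mu0U[s] ~ %s", lp(hy$mu0_U)))
  }

  # trial-level mean/SD (isC/isP/isU are 0-1 data vectors)
  tr <- c("yt[n] <- y[n] - h[subj[n]] * t[n]")
  mu0c <- "mu0C[subj[n], lev[n]] - h[subj[n]] * t[n]"
  mu0p <- if (info$free_mu0) "mu0P[subj[n], lev[n]] - h[subj[n]] * t[n]"
          else mu0c
  m0u <- switch(info$u_prior,
    dynamic = if (info$free_mu0)
      paste0("inprod(w[n, ], (mu0C[subj[n], ] + mu0P[subj[n], ]) / 2)")
    else "inprod(w[n, ], mu0C[subj[n], ])",
    fixed = "mu0U[subj[n]]",
    none = NULL)

  if (spec$variant == "null_hab") {
    tr <- c(tr, "mu[n] <- yt[n]", "sd[n] <- noise[subj[n]]")
  } else if (spec$variant == "null_means") {
    tr <- c(tr,
      sprintf("muCP[n] <- isP[n] * (%s) + (1 - isP[n]) * (%s)", mu0p, mu0c),
      "mu[n] <- isU[n] * yt[n] + (1 - isU[n]) * muCP[n]",
      "sd[n] <- isU[n] * noise[subj[n]] + (1 - isU[n]) * tau0[subj[n]]")
  } else if (info$multi_alpha) {
    mu0p_lev <- if (info$free_mu0) "mu0P[subj[n], lev[n]]"
                else "mu0C[subj[n], lev[n]]"
    tr <- c(tr,
      sprintf("m0u[n] <- %s", m0u),
      sprintf("prior[n] <- isU[n] * m0u[n] + isP[n] * (%s) + isC[n] * (%s)",
              mu0p_lev, "mu0C[subj[n], lev[n]]"),
      paste0("a[n] <- isU[n] * alphaU[subj[n]] + isP[n] * alphaP[subj[n]]",
             " + isC[n] * alphaC[subj[n]]"),
      "mu[n] <- prior[n] + a[n] * (yt[n] - prior[n])",
      "sd[n] <- tau1[subj[n]]")
  } else {
    sd_cp <- if (info$free_tau0)
      "isC[n] * tau0C[subj[n]] + isP[n] * tau0P[subj[n]]"
    else "(1 - isU[n]) * tau0[subj[n]]"
    tr <- c(tr,
      sprintf("m0u[n] <- %s", m0u),
      "muU[n] <- m0u[n] + alphaU[subj[n]] * (yt[n] - m0u[n])",
      sprintf("muCP[n] <- isP[n] * (%s) + isC[n] * (%s)", mu0p, mu0c),
      "mu[n] <- isU[n] * muU[n] + (1 - isU[n]) * muCP[n]",
      sprintf("sd[n] <- isU[n] * tau1[subj[n]] + %s", sd_cp))
  }

  paste0(
    "model {\n",
    paste0("  ", blocks, collapse = "\n"), if (length(blocks)) "\n",
    "  for (s in 1:S) {\n",
    paste0("    ", sub, collapse = "\n"), "\n  }\n",
    "  for (n in 1:N) {\n",
    paste0("    ", tr, collapse = "\n"), "\n",
    "    r[n] ~ dnorm(mu[n], pow(sd[n], -2)) T(0, 100)\n",
    "  }\n}\n")
}

# JAGS monitor names for a variant (subject- and group-level)
jags_monitors <- function(spec) {
  info <- spec$info
  c(if (info$has_mu0) c("gm", "sigma_mu0", "mu0C"),
    if (info$free_mu0) "mu0P",
    if (info$has_tau0 && !info$free_tau0) "tau0",
    if (info$free_tau0) c("tau0C", "tau0P"),
    if (info$has_tau1) "tau1",
    if (info$has_noise) "noise",
    if (info$has_alpha) "alphaU",
    if (info$multi_alpha) c("alphaC", "alphaP"),
    if (info$u_prior == "fixed") "mu0U",
    "h")
}

# data list for jags.model(); trials must already be reduced to scored rows
jags_data <- function(spec, pre, rating) {
  d <- list(N = length(rating), S = length(pre$subjects),
            subj = pre$s, lev = pre$lev, t = pre$t, y = pre$y,
            isC = as.numeric(pre$isC), isP = as.numeric(pre$isP),
            isU = as.numeric(pre$isU), r = rating,
            gm_mean = spec$hyper$mu0_mean)
  if (spec$info$u_prior == "dynamic") d$w <- pre$w
  if (spec$variant == "null_hab") {
    d$lev <- NULL; d$isC <- NULL; d$isP <- NULL; d$isU <- NULL
    d$gm_mean <- NULL
  }
  if (spec$variant == "null_means") d$isC <- NULL
  d
}

.chain_inits <- function(seed, chains) {
  lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(seed) %% 10000000L) * 100L + ch)
  })
}

#' Fit an observer-model variant hierarchically by MCMC
#'
#' Samples the hierarchical posterior of a model variant with JAGS:
#' subject-level prior means are partially pooled around group-level means
#' (one per intensity level) with pooling SD `sigma_mu0`; SD-type parameters
#' are sampled on the log scale; likelihood weights on a `[0,1]`-truncated
#' scale. Trials with missing ratings are dropped from the likelihood.
#' Split-R-hat and effective sample size are computed for every monitored
#' parameter; the fit is flagged (not rejected) if any split-R-hat reaches
#' 1.01.
#'
#' @param trials Trial tibble.
#' @param spec A [model_spec()] (or a variant name, which is promoted with
#'   default settings).
#' @param seed Integer seed; chains get derived RNG streams, so the same
#'   seed and data give identical draws.
#' @param quiet Suppress JAGS progress output.
#' @return A `pain_fit` object: posterior draws (`coda::mcmc.list`), the
#'   scored trials, diagnostics tibble, and a convergence flag.
#' @export
fit_hierarchical <- function(trials, spec, seed = 1, quiet = TRUE) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  pre_all <- .trial_precomp(tibble::as_tibble(trials), spec$variant)
  keep <- !is.na(pre_all$trials$rating)
  scored <- pre_all$trials[keep, ]
  if (nrow(scored) == 0) stop("No non-missing ratings to fit.", call. = FALSE)
  pre <- .trial_precomp(scored, spec$variant)
  data <- jags_data(spec, pre, scored$rating)

  mc <- spec$mcmc
  model <- rjags::jags.model(
    textConnection(jags_code(spec)), data = data,
    inits = .chain_inits(seed, mc$chains),
    n.chains = mc$chains, n.adapt = mc$adapt, quiet = quiet)
  stats::update(model, mc$warmup, progress.bar = "none")
  draws <- rjags::coda.samples(model, jags_monitors(spec),
                               n.iter = mc$iter - mc$warmup, thin = mc$thin,
                               progress.bar = "none")
  diagnostics <- mcmc_diagnostics(draws)
  structure(
    list(variant = spec$variant, spec = spec, draws = draws,
         trials = scored, subjects = pre$subjects, seed = seed,
         diagnostics = diagnostics,
         converged = all(diagnostics$rhat < 1.01, na.rm = TRUE)),
    class = "pain_fit")
}

#' @export
print.pain_fit <- function(x, ...) {
  cat("<pain_fit> variant:", x$variant, "\n",
      " subjects:", length(x$subjects),
      " scored trials:", nrow(x$trials), "\n",
      " chains:", length(x$draws),
      " draws/chain:", nrow(x$draws[[1]]), "\n",
      " converged (split-R-hat < 1.01):", x$converged,
      " (max R-hat ", round(max(x$diagnostics$rhat, na.rm = TRUE), 4), ")\n")
  invisible(x)
}

#' Split-R-hat and effective sample size for an mcmc.list
#'
#' Each chain is split in half before computing the potential scale
#' reduction factor, so within-chain drift is detected as well as
#' between-chain disagreement.
#'
#' @param draws A `coda::mcmc.list`.
#' @return Tibble with `parameter`, `rhat`, `ess`.
#' @export
mcmc_diagnostics <- function(draws) {
  mat <- lapply(draws, as.matrix)
  params <- colnames(mat[[1]])
  half <- floor(nrow(mat[[1]]) / 2)
  rhat <- vapply(params, function(p) {
    chains <- unlist(lapply(mat, function(m) {
      x <- m[, p]
      list(x[seq_len(half)], x[seq_len(half) + half])
    }), recursive = FALSE)
    split_rhat(chains)
  }, numeric(1))
  ess <- tryCatch(as.numeric(coda::effectiveSize(draws)[params]),
                  error = function(e) rep(NA_real_, length(params)))
  tibble::tibble(parameter = params, rhat = unname(rhat), ess = ess)
}

# chains: list of equal-length numeric vectors
split_rhat <- function(chains) {
  n <- length(chains[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Highest posterior density interval
#'
#' The narrowest contiguous interval over the sorted draws that contains
#' `ceiling(mass * n)` of them; ties are broken by the earliest window. For
#' unimodal posteriors this is the usual HPDI; for `mass -> 1` it approaches
#' `[min, max]`.
#'
#' @param draws Numeric vector of posterior draws (length >= 2).
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
hpdi <- function(draws, mass = 0.95) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 2) stop("Need at least 2 draws.", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("`mass` must be in (0, 1).", call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  lo_idx <- seq_len(n - m + 1)
  widths <- x[lo_idx + m - 1] - x[lo_idx]
  i <- which.min(widths) # which.min returns the earliest minimum
  c(lo = x[i], hi = x[i + m - 1])
}

# draws as one matrix (chains stacked), with a map from canonical parameter
# names to columns
.draws_matrix <- function(fit) {
  do.call(rbind, lapply(fit$draws, as.matrix))
}

# canonical per-subject parameter arrays for one draw (row of the stacked
# matrix); `cmap` is the precomputed column map from .column_map()
.column_map <- function(fit) {
  cols <- colnames(fit$draws[[1]])
  S <- length(fit$subjects)
  info <- fit$spec$info
  arr2 <- function(nm) {
    m <- outer(seq_len(S), 1:3,
               function(s, l) match(sprintf("%s[%d,%d]", nm, s, l), cols))
    if (anyNA(m)) NULL else m
  }
  vec <- function(nm) {
    v <- match(sprintf("%s[%d]", nm, seq_len(S)), cols)
    # a length-1 monitored vector loses its index in JAGS column names
    if (anyNA(v) && S == 1) v <- match(nm, cols)
    if (anyNA(v)) NULL else v
  }
  list(
    mu0_C = arr2("mu0C"),
    mu0_P = if (info$free_mu0) arr2("mu0P") else arr2("mu0C"),
    tau0 = vec("tau0"), tau0_C = vec("tau0C"), tau0_P = vec("tau0P"),
    tau1 = vec("tau1"), noise = vec("noise"),
    alpha_U = vec("alphaU"), alpha_C = vec("alphaC"),
    alpha_P = vec("alphaP"), h = vec("h"), mu0_U = vec("mu0U"))
}

.params_from_draw <- function(row, cmap) {
  lapply(cmap, function(ix) {
    if (is.null(ix)) return(NULL)
    if (is.matrix(ix)) matrix(row[ix], nrow = nrow(ix)) else row[ix]
  })
}

#' Posterior-mean subject parameters of a fit
#'
#' @param fit A `pain_fit`.
#' @return Tibble with one row per subject, columns named as in
#'   [sample_group_parameters()].
#' @export
subject_parameters <- function(fit) {
  mat <- .draws_matrix(fit)
  pm <- colMeans(mat)
  cmap <- .column_map(fit)
  P <- .params_from_draw(pm, cmap)
  out <- tibble::tibble(subject_id = fit$subjects)
  if (!is.null(P$mu0_C)) {
    out$mu0_C_30 <- P$mu0_C[, 1]; out$mu0_C_50 <- P$mu0_C[, 2]
    out$mu0_C_70 <- P$mu0_C[, 3]
    out$mu0_P_30 <- P$mu0_P[, 1]; out$mu0_P_50 <- P$mu0_P[, 2]
    out$mu0_P_70 <- P$mu0_P[, 3]
  }
  for (nm in c("tau0", "tau0_C", "tau0_P", "tau1", "alpha_U", "alpha_C",
               "alpha_P", "h", "mu0_U", "noise")) {
    if (!is.null(P[[nm]])) out[[nm]] <- P[[nm]]
  }
  out
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Evaluates, for a subsample of posterior draws, the truncated-normal log
#' density of every scored rating under the draw's subject parameters (via
#' the same predictive core the generator uses). Rows are draws, columns are
#' trials, aligned with `fit$trials`.
#'
#' @param fit A `pain_fit`.
#' @param ndraws Maximum number of draws to score (evenly thinned across the
#'   stacked chains).
#' @return Matrix (draws x trials) with attribute `draw_index`.
#' @export
loglik_matrix <- function(fit, ndraws = 1000) {
  mat <- .draws_matrix(fit)
  idx <- if (nrow(mat) > ndraws) {
    unique(round(seq(1, nrow(mat), length.out = ndraws)))
  } else {
    seq_len(nrow(mat))
  }
  cmap <- .column_map(fit)
  pre <- .trial_precomp(fit$trials, fit$variant)
  r <- fit$trials$rating
  ll <- matrix(NA_real_, nrow = length(idx), ncol = length(r))
  for (j in seq_along(idx)) {
    P <- .params_from_draw(mat[idx[j], ], cmap)
    ms <- .pred_core(fit$variant, P, pre)
    ll[j, ] <- dtrunc_normal(r, ms$mu, ms$sd, log = TRUE)
  }
  attr(ll, "draw_index") <- idx
  ll
}

#' Posterior-predictive ratings
#'
#' For each retained posterior draw, draws one predicted rating per trial
#' from the trial's truncated-normal predictive distribution.
#'
#' @param fit A `pain_fit`.
#' @param newdata Optional trial tibble (defaults to the fitted trials).
#' @param ndraws Number of posterior draws to use.
#' @param seed Optional integer seed for the predictive draws.
#' @return Tibble in long format: `.draw`, the trial identifiers, and
#'   `prediction` in `[0, 100]`.
#' @export
posterior_predict <- function(fit, newdata = NULL, ndraws = 200,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- if (is.null(newdata)) fit$trials else tibble::as_tibble(newdata)
  mat <- .draws_matrix(fit)
  idx <- if (nrow(mat) > ndraws) {
    unique(round(seq(1, nrow(mat), length.out = ndraws)))
  } else {
    seq_len(nrow(mat))
  }
  cmap <- .column_map(fit)
  pre <- .trial_precomp(trials, fit$variant)
  if (!all(pre$subjects %in% fit$subjects)) {
    stop("`newdata` contains subjects absent from the fit.", call. = FALSE)
  }
  smap <- match(pre$subjects, fit$subjects)
  out <- purrr::map_dfr(seq_along(idx), function(j) {
    P <- .params_from_draw(mat[idx[j], ], cmap)
    P <- lapply(P, function(a) {
      if (is.null(a)) NULL else if (is.matrix(a)) a[smap, , drop = FALSE]
      else a[smap]
    })
    ms <- .pred_core(fit$variant, P, pre)
    tibble::tibble(.draw = j,
                   subject_id = trials$subject_id, run = trials$run,
                   trial = trials$trial, condition = trials$condition,
                   intensity_level = trials$intensity_level,
                   prediction = rtrunc_normal(nrow(trials), ms$mu, ms$sd))
  })
  out
}

#' Simulate-and-refit parameter recovery
#'
#' Simulates a dataset from a variant, refits it, and correlates the
#' generating subject-level parameter values with their posterior means.
#' Parameters whose correlation falls below `threshold` are flagged as not
#' recovered.
#'
#' @param variant One of [model_variants()].
#' @param n_subjects Number of simulated subjects (60 matches the empirical
#'   sample size; smaller values give a faster, noisier check).
#' @param group Generating group parameters (see
#'   [sample_group_parameters()]).
#' @param mcmc MCMC profile for the refit (default `"recovery"`).
#' @param threshold Recovery correlation threshold (default 0.7).
#' @param seed Integer seed.
#' @return A `recovery_report`: correlation table, scatter data, the fit and
#'   the simulated data.
#' @export
parameter_recovery <- function(variant, n_subjects = 60, group = NULL,
                               mcmc = "recovery", threshold = 0.7,
                               seed = 1) {
  variant <- .check_variant(variant)
  sim <- simulate_dataset(variant, n_subjects = n_subjects, group = group,
                          seed = seed)
  truth <- true_parameters(sim)
  fit <- fit_hierarchical(sim, model_spec(variant, mcmc = mcmc),
                          seed = seed + 1)
  est <- subject_parameters(fit)
  pars <- intersect(variant_info(variant)$free_params,
                    intersect(names(truth), names(est)))
  ord <- match(truth$subject_id, est$subject_id)
  scatter <- purrr::map_dfr(pars, function(p) {
    tibble::tibble(parameter = p, subject_id = truth$subject_id,
                   truth = truth[[p]], estimate = est[[p]][ord])
  })
  table <- scatter |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      r = if (stats::sd(.data$truth) > 0 && stats::sd(.data$estimate) > 0)
        stats::cor(.data$truth, .data$estimate) else NA_real_,
      n_subjects = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(recovered = !is.na(.data$r) & .data$r >= threshold)
  structure(list(variant = variant, table = table, scatter = scatter,
                 threshold = threshold, converged = fit$converged,
                 fit = fit, data = sim),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> variant:", x$variant,
      " threshold r >=", x$threshold, "\n")
  print(x$table)
  invisible(x)
}
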