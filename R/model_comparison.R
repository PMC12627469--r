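# Leave-one-out model comparison: pointwise ELPD via Pareto-smoothed
# importance sampling, a robust mixture estimator that stays finite when the
# importance weights are heavy-tailed, an exact refit oracle for small data,
# and paired comparison with the SE of the ELPD difference.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Generalized-Pareto tail fit
#'
#' Profile-likelihood fit of the generalized Pareto distribution to tail
#' exceedances (Zhang & Stephens 2009 estimator with a weak prior pulling
#' the shape towards 0.5), as used to smooth importance weights.
#'
#' @param x Positive exceedances.
#' @return List with shape `k` and scale `sigma`.
#' @export
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) stop("Need at least 5 tail exceedances.", call. = FALSE)
  m <- 30L + floor(sqrt(n))
  j <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * x[floor(n / 4 + 0.5)])
  k_of <- vapply(theta, function(b) mean(log1p(-b * x)), numeric(1))
  ll <- n * (log(-theta / k_of) - k_of - 1)
  wts <- 1 / vapply(j, function(i) sum(exp(ll - ll[i])), numeric(1))
  b <- sum(theta * wts)
  k <- mean(log1p(-b * x))
  sigma <- -k / b
  # weakly informative prior on the shape (10 pseudo-observations at 0.5)
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

.elpd_result <- function(pointwise, method, pareto_k = NULL) {
  n <- length(pointwise)
  structure(
    list(elpd = sum(pointwise), pointwise = pointwise,
         se = sqrt(n * var(pointwise)), pareto_k = pareto_k,
         method = method, n = n),
    class = "elpd_result")
}

#' @export
print.elpd_result <- function(x, ...) {
  cat("<elpd_result> method:", x$method, "\n",
      " elpd:", round(x$elpd, 2), " se:", round(x$se, 2),
      " n:", x$n, "\n")
  if (!is.null(x$pareto_k)) {
    cat("  pareto k > 0.7:", sum(x$pareto_k > 0.7), "of", x$n, "\n")
  }
  invisible(x)
}

#' Leave-one-out ELPD via Pareto-smoothed importance sampling
#'
#' Estimates, for every observation, the log predictive density it would
#' have under the posterior fitted without it, by importance-reweighting the
#' full-posterior draws. The raw importance ratios `1/p(y_i | theta)` are
#' smoothed by replacing their upper tail with quantiles of a fitted
#' generalized Pareto distribution; the fitted shape `k` is reported per
#' observation, and values above `k_threshold` mark observations whose
#' estimate is unreliable.
#'
#' @param loglik Matrix of pointwise log-likelihoods (draws x observations),
#'   e.g. from [loglik_matrix()]. At least 100 draws.
#' @param k_threshold Reliability threshold for the Pareto shape
#'   (default 0.7).
#' @return An `elpd_result` with `pointwise`, `se` and `pareto_k`.
#' @export
psis_loo <- function(loglik, k_threshold = 0.7) {
  stopifnot(is.matrix(loglik), all(is.finite(loglik)))
  S <- nrow(loglik)
  if (S < 100) stop("Need at least 100 draws for the tail fit.",
                    call. = FALSE)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  pointwise <- numeric(ncol(loglik))
  ks <- numeric(ncol(loglik))
  for (i in seq_len(ncol(loglik))) {
    lr <- -loglik[, i]           # log importance ratios
    lr <- lr - max(lr)
    ord <- order(lr)
    tail_ids <- ord[(S - M + 1):S]
    cutoff <- lr[ord[S - M]]
    exceed <- exp(lr[tail_ids]) - exp(cutoff)
    k <- NA_real_
    if (length(unique(exceed)) >= 5) {
      fitp <- gpd_fit(exceed)
      k <- fitp$k
      pq <- (seq_len(M) - 0.5) / M
      smoothed <- log(qgpd(pq, fitp$k, fitp$sigma) + exp(cutoff))
      lr[tail_ids[order(lr[tail_ids])]] <- pmin(smoothed, 0)
    }
    ks[i] <- k
    pointwise[i] <- logsumexp(lr + loglik[, i]) - logsumexp(lr)
  }
  res <- .elpd_result(pointwise, "psis", pareto_k = ks)
  res$k_threshold <- k_threshold
  res$unreliable <- which(!is.na(ks) & ks > k_threshold)
  res
}

# inits for the mixture chain: posterior means of the original fit mapped
# back to the sampled (log / truncated) scales
.mixture_inits <- function(fit, seed, chains) {
  pm <- colMeans(.draws_matrix(fit))
  cols <- names(pm)
  S <- length(fit$subjects)
  info <- fit$spec$info
  take_vec <- function(nm) {
    v <- pm[match(sprintf("%s[%d]", nm, seq_len(S)), cols)]
    if (anyNA(v) && S == 1) v <- pm[match(nm, cols)]
    if (anyNA(v)) NULL else unname(v)
  }
  take_mat <- function(nm) {
    m <- outer(seq_len(S), 1:3,
               function(s, l) pm[match(sprintf("%s[%d,%d]", nm, s, l), cols)])
    if (anyNA(m)) NULL else unname(m)
  }
  base <- list()
  if (info$has_mu0) {
    base$gm <- unname(pm[match(sprintf("gm[%d]", 1:3), cols)])
    base$lsig_mu0 <- log(unname(pm[match("sigma_mu0", cols)]))
    base$mu0C <- take_mat("mu0C")
    if (info$free_mu0) base$mu0P <- take_mat("mu0P")
  }
  if (!is.null(take_vec("tau0"))) base$lt0 <- log(take_vec("tau0"))
  if (!is.null(take_vec("tau0C"))) base$lt0C <- log(take_vec("tau0C"))
  if (!is.null(take_vec("tau0P"))) base$lt0P <- log(take_vec("tau0P"))
  if (!is.null(take_vec("tau1"))) base$lt1 <- log(take_vec("tau1"))
  if (!is.null(take_vec("noise"))) base$lno <- log(take_vec("noise"))
  if (!is.null(take_vec("alphaU"))) {
    base$alphaU <- pmin(pmax(take_vec("alphaU"), 0.01), 0.99)
  }
  if (info$multi_alpha && !is.null(take_vec("alphaC"))) {
    base$alphaC <- pmin(pmax(take_vec("alphaC"), 0.01), 0.99)
  }
  if (fit$variant == "three_alpha" && !is.null(take_vec("alphaP"))) {
    base$alphaP <- pmin(pmax(take_vec("alphaP"), 0.01), 0.99)
  }
  base$h <- take_vec("h")
  if (info$u_prior == "fixed") base$mu0U <- take_vec("mu0U")
  lapply(seq_len(chains), function(ch) {
    c(base, list(.RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = (abs(seed) %% 10000000L) * 100L + ch))
  })
}

#' Robust leave-one-out ELPD via a mixture estimator
#'
#' Instead of reweighting full-posterior draws (whose importance ratios can
#' have infinite variance), this estimator samples a single auxiliary chain
#' whose target is proportional to the posterior times
#' `sum_i 1 / p(y_i | theta)` -- an equal-weight mixture of all
#' leave-one-out posteriors. Under that mixture the per-observation weights
#' are bounded by construction, so every pointwise ELPD is finite without
#' any tail diagnostic. Costs one extra MCMC run of the same model.
#'
#' @param fit A `pain_fit`.
#' @param mcmc MCMC profile for the auxiliary chain (defaults to the fit's
#'   own settings).
#' @param ndraws Maximum mixture draws used in the estimator.
#' @param seed Integer seed.
#' @param quiet Suppress JAGS output.
#' @return An `elpd_result` with method `"robust_mixture"`.
#' @export
robust_loo <- function(fit, mcmc = NULL, ndraws = 2000, seed = 1,
                       quiet = TRUE) {
  spec <- fit$spec
  if (!is.null(mcmc)) spec$mcmc <- mcmc_profile(mcmc)
  pre <- .trial_precomp(fit$trials, fit$variant)
  data <- jags_data(spec, pre, fit$trials$rating)

  # typical scale of -loglik, used to keep the summed mixture factor in
  # floating range inside JAGS
  ll0 <- loglik_matrix(fit, ndraws = 200)
  shiftK <- max(-ll0)
  data$shiftK <- shiftK
  data$Cbig <- shiftK + 600
  data$zero <- 0
  data$rr <- fit$trials$rating

  code <- jags_code(spec)
  mix <- paste0(
    "  for (n in 1:N) {\n",
    "    ldp[n] <- logdensity.norm(rr[n], mu[n], pow(sd[n], -2))",
    " - log(pnorm(100, mu[n], pow(sd[n], -2))",
    " - pnorm(0, mu[n], pow(sd[n], -2)))\n",
    "    es[n] <- exp(max(min(-ldp[n] - shiftK, 500), -500))\n",
    "  }\n",
    "  phi <- Cbig - shiftK - log(sum(es))\n",
    "  zero ~ dpois(phi)\n}")
  code <- paste0(substr(code, 1, nchar(code) - 2), mix, "\n")

  mc <- spec$mcmc
  model <- rjags::jags.model(
    textConnection(code), data = data,
    inits = .mixture_inits(fit, seed, mc$chains),
    n.chains = mc$chains, n.adapt = mc$adapt, quiet = quiet)
  stats::update(model, mc$warmup, progress.bar = "none")
  draws <- rjags::coda.samples(model, jags_monitors(spec),
                               n.iter = mc$iter - mc$warmup, thin = mc$thin,
                               progress.bar = "none")

  mixfit <- fit
  mixfit$draws <- draws
  ll <- loglik_matrix(mixfit, ndraws = ndraws)   # draws from the mixture
  log_s <- apply(ll, 1, function(row) logsumexp(-row))
  a <- logsumexp(-log_s)
  pointwise <- vapply(seq_len(ncol(ll)), function(i) {
    a - logsumexp(-ll[, i] - log_s)
  }, numeric(1))
  .elpd_result(pointwise, "robust_mixture")
}

#' Exact leave-one-out ELPD by refitting
#'
#' The ground-truth oracle for the estimators: refits the model once per
#' observation, leaving that observation out, and evaluates its log
#' predictive density under the held-out posterior. Only sensible for small
#' datasets, hence the trial cap.
#'
#' @param trials Trial tibble.
#' @param spec A [model_spec()] (or variant name).
#' @param seed Integer seed (each refit gets a derived seed).
#' @param cap Maximum number of scored trials (default 200).
#' @param ndraws Draws used to evaluate each held-out density.
#' @return An `elpd_result` with method `"exact_refit"`.
#' @export
exact_refit_loo <- function(trials, spec, seed = 1, cap = 200,
                            ndraws = 1000) {
  if (is.character(spec)) spec <- model_spec(spec)
  trials <- tibble::as_tibble(trials)
  if (spec$info$u_prior == "dynamic") {
    trials <- add_dynamic_weights(trials)
  }
  scored_idx <- which(!is.na(trials$rating))
  n <- length(scored_idx)
  if (n > cap) {
    stop("Exact refit LOO capped at ", cap, " scored trials (got ", n, ").",
         call. = FALSE)
  }
  pointwise <- vapply(seq_len(n), function(i) {
    hold <- trials[scored_idx[i], ]
    rest <- trials[-scored_idx[i], ]
    f <- fit_hierarchical(rest, spec, seed = seed + i, quiet = TRUE)
    ll <- .loglik_newdata(f, hold, ndraws = ndraws)
    logsumexp(ll[, 1]) - log(nrow(ll))
  }, numeric(1))
  .elpd_result(pointwise, "exact_refit")
}

# pointwise log-likelihood of new trials under a fit's posterior draws
.loglik_newdata <- function(fit, newtrials, ndraws = 1000) {
  mat <- .draws_matrix(fit)
  idx <- if (nrow(mat) > ndraws) {
    unique(round(seq(1, nrow(mat), length.out = ndraws)))
  } else {
    seq_len(nrow(mat))
  }
  cmap <- .column_map(fit)
  pre <- .trial_precomp(newtrials, fit$variant)
  smap <- match(pre$subjects, fit$subjects)
  if (anyNA(smap)) {
    stop("New trials contain subjects absent from the fit.", call. = FALSE)
  }
  r <- newtrials$rating
  ll <- matrix(NA_real_, length(idx), length(r))
  for (j in seq_along(idx)) {
    P <- .params_from_draw(mat[idx[j], ], cmap)
    P <- lapply(P, function(a) {
      if (is.null(a)) NULL else if (is.matrix(a)) a[smap, , drop = FALSE]
      else a[smap]
    })
    ms <- .pred_core(fit$variant, P, pre)
    ll[j, ] <- dtrunc_normal(r, ms$mu, ms$sd, log = TRUE)
  }
  ll
}

#' Compare two ELPD results
#'
#' Pairwise model comparison on the same observations: the ELPD difference,
#' the standard error of the difference computed from the pointwise
#' differences, and a verdict -- `"small"` when `|diff| < 4` (differences
#' below 4 are conventionally negligible), otherwise the better model's
#' label, qualified by whether `|diff|` exceeds twice its SE.
#'
#' @param a,b `elpd_result` objects over the same trials.
#' @param labels Length-2 character labels for the two models.
#' @return An `elpd_comparison`: `elpd_diff` (a minus b), `se_diff`,
#'   `verdict`, `reliable`, and the pointwise differences.
#' @export
compare_elpd <- function(a, b, labels = c("a", "b")) {
  stopifnot(inherits(a, "elpd_result"), inherits(b, "elpd_result"))
  if (a$n != b$n) stop("ELPD results cover different trial sets.",
                       call. = FALSE)
  pd <- a$pointwise - b$pointwise
  diff <- sum(pd)
  se_diff <- sqrt(length(pd) * var(pd))
  verdict <- if (abs(diff) < 4) "small"
             else if (diff > 0) labels[1] else labels[2]
  structure(
    list(elpd_diff = diff, se_diff = se_diff, verdict = verdict,
         reliable = abs(diff) > 2 * se_diff, labels = labels,
         pointwise_diff = pd, n = length(pd)),
    class = "elpd_comparison")
}

#' @export
print.elpd_comparison <- function(x, ...) {
  cat("<elpd_comparison> ", x$labels[1], " - ", x$labels[2], ": ",
      round(x$elpd_diff, 2), " (se ", round(x$se_diff, 2), ")\n",
      "  verdict: ", x$verdict,
      if (x$verdict != "small") {
        if (x$reliable) " (|diff| > 2 se)" else " (|diff| <= 2 se)"
      }, "\n", sep = "")
  invisible(x)
}
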