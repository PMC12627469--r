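# Broom-style tidy() / glance() methods for the fitted objects.

#' @rdname pain_tidiers
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.pain_fit <- function(x, ...) {
  mat <- .draws_matrix(x)
  purrr::map_dfr(colnames(mat), function(p) {
    hp <- hpdi(mat[, p])
    tibble::tibble(term = p, mean = mean(mat[, p]),
                   hpdi_lo = hp[["lo"]], hpdi_hi = hp[["hi"]])
  }) |>
    dplyr::left_join(dplyr::rename(x$diagnostics, term = "parameter"),
                     by = "term")
}

#' Tidy and glance methods
#'
#' `tidy()` returns per-term posterior summaries (mean, 95% HPDI, and where
#' available split-R-hat and effective sample size); `glance()` one-row fit
#' summaries.
#'
#' @name pain_tidiers
NULL

#' @rdname pain_tidiers
#' @export
glance.pain_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 n_subjects = length(x$subjects),
                 n_trials = nrow(x$trials),
                 chains = length(x$draws),
                 draws = nrow(x$draws[[1]]) * length(x$draws),
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 converged = x$converged)
}

#' @rdname pain_tidiers
#' @param contrasts For `pain_lmm` objects: return the assembled pairwise
#'   contrasts instead of the raw coefficients.
#' @export
tidy.pain_lmm <- function(x, contrasts = FALSE, ...) {
  if (contrasts) {
    if (is.null(x$pairwise)) {
      stop("This fit carries no pairwise contrasts.", call. = FALSE)
    }
    return(x$pairwise)
  }
  x$coefficients
}

#' @rdname pain_tidiers
#' @export
glance.pain_lmm <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, baseline = x$baseline,
                 n_terms = nrow(x$coefficients),
                 max_rhat = max(x$coefficients$rhat, na.rm = TRUE),
                 converged = x$converged)
}

#' @rdname pain_tidiers
#' @export
tidy.elpd_result <- function(x, ...) {
  tibble::tibble(trial = seq_len(x$n), elpd = x$pointwise,
                 pareto_k = if (is.null(x$pareto_k)) NA_real_ else
                   x$pareto_k)
}

#' @rdname pain_tidiers
#' @export
glance.elpd_result <- function(x, ...) {
  tibble::tibble(method = x$method, elpd = x$elpd, se = x$se, n = x$n,
                 n_high_k = if (is.null(x$pareto_k)) NA_integer_ else
                   sum(x$pareto_k > 0.7, na.rm = TRUE))
}

#' @rdname pain_tidiers
#' @export
tidy.elpd_comparison <- function(x, ...) {
  tibble::tibble(model_a = x$labels[1], model_b = x$labels[2],
                 elpd_diff = x$elpd_diff, se_diff = x$se_diff,
                 verdict = x$verdict, reliable = x$reliable)
}

#' @rdname pain_tidiers
#' @export
tidy.recovery_report <- function(x, ...) {
  x$table
}

#' @rdname pain_tidiers
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 min_r = min(x$table$r, na.rm = TRUE),
                 all_recovered = all(x$table$recovered),
                 threshold = x$threshold, converged = x$converged)
}

#' @rdname pain_tidiers
#' @export
tidy.pain_choice_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname pain_tidiers
#' @export
glance.pain_choice_fit <- function(x, ...) {
  tibble::tibble(level = x$level, degree = x$degree, elpd = x$elpd$elpd,
                 elpd_se = x$elpd$se, converged = x$converged)
}
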