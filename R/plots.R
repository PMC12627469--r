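# ggplot2 figures for the main result types.

.condition_fills <- c(C = "#1b7837", P = "#a6dba0", U = "#fdb863")

#' Boxplot of ratings by intensity and condition
#'
#' @param trials Trial tibble.
#' @return A ggplot object.
#' @export
plot_ratings <- function(trials) {
  d <- dplyr::filter(tibble::as_tibble(trials), !is.na(.data$rating))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$intensity_level),
                                  .data$rating,
                                  fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_fill_manual(values = .condition_fills) +
    ggplot2::labs(x = "Intensity level (VAS target)", y = "Pain rating",
                  fill = "Condition") +
    ggplot2::theme_minimal()
}

#' Within-subject rating SDs with corrected SEM bars
#'
#' Mean within-subject rating standard deviation per condition (or per
#' intensity level), with standard errors corrected for the within-subject
#' design via [within_subject_sem()].
#'
#' @param sd_table Output of [within_subject_sd_table()].
#' @param by `"condition"` or `"intensity"`.
#' @return A ggplot object.
#' @export
plot_rating_sd <- function(sd_table, by = c("condition", "intensity")) {
  by <- match.arg(by)
  d <- dplyr::filter(tibble::as_tibble(sd_table), !is.na(.data$sd))
  cells <- if (by == "condition") {
    d |>
      dplyr::group_by(.data$subject_id, .data$condition) |>
      dplyr::summarise(sd = mean(.data$sd), .groups = "drop") |>
      within_subject_sem(.data$sd, .data$subject_id, .data$condition) |>
      dplyr::rename(x = "condition")
  } else {
    d |>
      dplyr::group_by(.data$subject_id, .data$intensity_level) |>
      dplyr::summarise(sd = mean(.data$sd), .groups = "drop") |>
      within_subject_sem(.data$sd, .data$subject_id,
                         .data$intensity_level) |>
      dplyr::mutate(x = factor(.data$intensity_level)) |>
      dplyr::select(-"intensity_level")
  }
  ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = if (by == "condition") "Condition" else
      "Intensity level",
      y = "Within-subject rating SD (mean ± corrected SEM)") +
    ggplot2::theme_minimal()
}

#' Choice frequencies over trial positions
#'
#' @param choice_table Output of [choice_percentages()].
#' @return A ggplot object.
#' @export
plot_choice_frequencies <- function(choice_table) {
  ggplot2::ggplot(tibble::as_tibble(choice_table),
                  ggplot2::aes(.data$trial, .data$percent,
                               colour = factor(.data$intensity_level))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Trial position in run", y = "% chosen",
                  colour = "Level") +
    ggplot2::theme_minimal()
}

#' ELPD model comparison plot
#'
#' @param elpds Named list of `elpd_result` objects.
#' @return A ggplot object (ELPD with +/- 1 SE bars, best model on top).
#' @export
plot_model_comparison <- function(elpds) {
  d <- purrr::map_dfr(names(elpds), function(nm) {
    tibble::tibble(model = nm, elpd = elpds[[nm]]$elpd,
                   se = elpds[[nm]]$se)
  }) |>
    dplyr::arrange(.data$elpd) |>
    dplyr::mutate(model = factor(.data$model, levels = .data$model))
  ggplot2::ggplot(d, ggplot2::aes(.data$elpd, .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$elpd - .data$se,
                                          xmax = .data$elpd + .data$se)) +
    ggplot2::labs(x = "ELPD (higher = better out-of-sample fit)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pain_autoplots
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$scatter,
                  ggplot2::aes(.data$truth, .data$estimate)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Generating value", y = "Posterior mean",
                  title = paste("Parameter recovery:", object$variant)) +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` on a `recovery_report` draws truth-versus-estimate scatter
#' panels; on a `pain_fit` it draws posterior densities of the group-level
#' parameters; on a `pain_lmm` a coefficient interval plot.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @name pain_autoplots
NULL

#' @rdname pain_autoplots
#' @export
autoplot.pain_fit <- function(object, ...) {
  mat <- .draws_matrix(object)
  keep <- grep("^gm\\[|^sigma_mu0$", colnames(mat), value = TRUE)
  if (length(keep) == 0) keep <- colnames(mat)[seq_len(min(4, ncol(mat)))]
  d <- purrr::map_dfr(keep, function(p) {
    tibble::tibble(parameter = p, value = mat[, p])
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$value)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Posterior draw", y = "Density") +
    ggplot2::theme_minimal()
}

#' @rdname pain_autoplots
#' @export
autoplot.pain_lmm <- function(object, ...) {
  d <- if (!is.null(object$pairwise)) object$pairwise else
    object$coefficients
  ggplot2::ggplot(d, ggplot2::aes(.data$mean,
                                  stats::reorder(.data$term, .data$mean))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hpdi_lo,
                                          xmax = .data$hpdi_hi)) +
    ggplot2::labs(x = "Posterior mean (95% HPDI)", y = NULL) +
    ggplot2::theme_minimal()
}
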