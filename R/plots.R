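# ggplot2 displays for the main result types.

#' Plot typical exposure versus age
#'
#' Displays AUC (or peak concentration) across the age range for the output
#' of [run_typical_curves()] or [typical_exposure_vs_age()]; ages where the
#' clearance model extrapolates below the observed range are drawn dashed.
#'
#' @param curves Tibble from [typical_exposure_vs_age()] or
#'   [run_typical_curves()].
#' @param quantity `"auc"` or `"cmax"`.
#' @return A ggplot object.
#' @export
plot_exposure_vs_age <- function(curves, quantity = c("auc", "cmax")) {
  quantity <- match.arg(quantity)
  lab <- if (quantity == "auc") "typical AUC (ug/L*h)" else "typical c_max (ug/L)"
  if (!"regimen" %in% names(curves)) curves$regimen <- "regimen"
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$age, y = .data[[quantity]],
                               colour = .data$regimen,
                               linetype = .data$extrapolated)) +
    ggplot2::geom_line(ggplot2::aes(
      group = interaction(.data$regimen, .data$rule, .data$extrapolated))) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "age (years)", y = lab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dose-versus-age profile with its rule boundaries
#'
#' @param profile Tibble from [dose_vs_age_profile()].
#' @return A ggplot object; vertical dotted lines mark rule changes.
#' @export
plot_dose_vs_age <- function(profile) {
  steps <- attr(profile, "discontinuities")
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$age, y = .data$dose_mg)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$rule, colour = .data$rule)) +
    ggplot2::labs(x = "age (years)", y = "administered dose (mg)",
                  colour = "rule") +
    ggplot2::theme_minimal()
  if (length(steps) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = steps, linetype = "dotted")
  }
  p
}

#' @describeIn plot_cohort_evaluation autoplot method.
#' @exportS3Method ggplot2::autoplot
autoplot.dox_cohort_evaluation <- function(object, ...) {
  plot_cohort_evaluation(object, ...)
}

#' Plot observed versus adapted normalised exposure
#'
#' Box-and-jitter display of the normalised AUC (percent of target) under
#' conventional protocol dosing and under the model-based adaptation, with
#' the target (100%) and the 80--125% window marked.
#'
#' @param object A `dox_cohort_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_cohort_evaluation <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(strategy = "observed",
                   normalised_auc = object$observed$normalised_auc),
    tibble::tibble(strategy = "adapted",
                   normalised_auc = object$adapted$normalised_auc)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strategy,
                                   y = .data$normalised_auc)) +
    ggplot2::geom_hline(yintercept = 100, colour = "red", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$window, colour = "red",
                        linetype = "dotted") +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "AUC, % of target") +
    ggplot2::theme_minimal()
}
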