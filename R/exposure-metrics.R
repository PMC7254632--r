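# Bias, precision, target attainment and exact quantile confidence intervals
# for exposure distributions.

#' Prediction errors of exposures against a target
#'
#' @param auc Achieved AUC values (ug/L*h), non-empty.
#' @param target Target AUC (> 0), same units.
#' @return Percent prediction errors `100 * (auc - target) / target`.
#' @examples
#' prediction_errors(c(80, 100, 125), 100)
#' @export
prediction_errors <- function(auc, target) {
  if (length(auc) == 0) stop("`auc` must be non-empty", call. = FALSE)
  if (target <= 0) stop("`target` must be positive", call. = FALSE)
  100 * (auc - target) / target
}

#' Median prediction error and median absolute prediction error
#'
#' Bias and precision of a set of percent prediction errors, summarised by
#' medians (Sheiner/Beal-style robust summaries): `mpe = median(PE)` and
#' `mape = median(|PE|)`. For even n the median is the mean of the two
#' central order statistics.
#'
#' @param pe Percent prediction errors, non-empty.
#' @return One-row tibble with `mpe` and `mape` (both percent).
#' @examples
#' bias_precision(c(-20, 0, 25))
#' @export
bias_precision <- function(pe) {
  if (length(pe) == 0) stop("`pe` must be non-empty", call. = FALSE)
  tibble::tibble(mpe = stats::median(pe), mape = stats::median(abs(pe)))
}

#' Target attainment within a percent window
#'
#' Fraction of normalised exposures inside the (inclusive) window, by default
#' the 80--125% bioequivalence range around the target.
#'
#' @param normalised_auc Normalised AUC values in percent of target.
#' @param window Lower and upper bounds in percent (inclusive).
#' @return Proportion in \[0, 1\].
#' @examples
#' attainment(c(79.9, 80, 125, 125.1))
#' @export
attainment <- function(normalised_auc, window = c(80, 125)) {
  if (length(normalised_auc) == 0) stop("input must be non-empty", call. = FALSE)
  mean(normalised_auc >= window[1] & normalised_auc <= window[2])
}

#' Exact (binomial) confidence interval for a quantile
#'
#' Distribution-free order-statistic interval: the number of observations at
#' or below the true q-quantile is Binomial(n, q), so the pair of order
#' statistics `(x_(l), x_(u))` covers the quantile with probability
#' `P(l <= Bin(n, q) <= u - 1)`. The symmetric-tail construction is used:
#' `l` is the largest index with `P(Bin < l) <= (1 - level)/2` and `u` the
#' smallest with `P(Bin >= u) <= (1 - level)/2`; realised coverage is then
#' at least `level`.
#'
#' @param values Sample, length n.
#' @param q Quantile in (0, 1); default the median.
#' @param level Nominal confidence level; default 0.95.
#' @return One-row tibble with `lower`, `upper` (data values), the order-
#'   statistic indices `l`, `u`, and the realised `coverage`.
#' @examples
#' quantile_ci(rnorm(100))
#' @export
quantile_ci <- function(values, q = 0.5, level = 0.95) {
  n <- length(values)
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  cdf <- stats::pbinom(seq_len(n) - 1, n, q)
  lower_ok <- which(cdf <= alpha / 2)        # P(Bin < l) <= alpha/2
  upper_ok <- which(1 - cdf <= alpha / 2)    # P(Bin >= u) <= alpha/2
  if (length(lower_ok) == 0 || length(upper_ok) == 0) {
    stop(sprintf("n = %d is too small for a %.0f%% quantile interval", n, 100 * level),
         call. = FALSE)
  }
  l <- max(lower_ok)
  u <- min(upper_ok)
  if (u < l) stop("degenerate interval: increase n or lower the level", call. = FALSE)
  s <- sort(values)
  tibble::tibble(
    lower = s[l], upper = s[u], l = l, u = u,
    coverage = stats::pbinom(u - 1, n, q) - stats::pbinom(l - 1, n, q)
  )
}

#' Paired comparison of two dosing strategies
#'
#' Delegates to the standard tests: Wilcoxon signed-rank for continuous
#' paired data and McNemar's chi-squared for paired binary flags (such as
#' target attainment before/after adaptation).
#'
#' @param before,after Paired observations of equal length; numeric for
#'   `kind = "continuous"`, logical/0-1 for `kind = "binary"`.
#' @param kind `"continuous"` or `"binary"`.
#' @return The p-value.
#' @examples
#' compare_paired(rnorm(20), rnorm(20, 1), "continuous")
#' @export
compare_paired <- function(before, after, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (length(before) != length(after)) {
    stop("`before` and `after` must be the same length", call. = FALSE)
  }
  if (kind == "continuous") {
    if (all(before == after)) return(1)
    suppressWarnings(stats::wilcox.test(before, after, paired = TRUE)$p.value)
  } else {
    tab <- table(factor(as.logical(before), c(FALSE, TRUE)),
                 factor(as.logical(after), c(FALSE, TRUE)))
    if (tab[1, 2] + tab[2, 1] == 0) return(1)
    suppressWarnings(stats::mcnemar.test(tab)$p.value)
  }
}

#' Full evaluation of an exposure distribution against a target
#'
#' Bundles prediction errors, bias/precision with exact median confidence
#' intervals, and 80--125% target attainment into one report.
#'
#' @param auc Achieved AUC values (ug/L*h).
#' @param target Target AUC (ug/L*h) or a [reference_target()].
#' @param window Attainment window in percent; default `c(80, 125)`.
#' @param level Confidence level for the quantile CIs.
#' @return A `dox_evaluation` object; see [tidy.dox_evaluation()] and
#'   [glance.dox_evaluation()].
#' @examples
#' evaluation_report(rnorm(100, 344, 50), 344)
#' @export
evaluation_report <- function(auc, target, window = c(80, 125), level = 0.95) {
  t <- if (inherits(target, "dox_reference_target")) target$target_auc else target
  pe <- prediction_errors(auc, t)
  bp <- bias_precision(pe)
  mpe_ci <- quantile_ci(pe, 0.5, level)
  mape_ci <- quantile_ci(abs(pe), 0.5, level)
  structure(
    list(
      n = length(auc), target = t, window = window, level = level,
      normalised_auc = 100 * auc / t,
      pe = pe,
      mpe = bp$mpe, mpe_lower = mpe_ci$lower, mpe_upper = mpe_ci$upper,
      mape = bp$mape, mape_lower = mape_ci$lower, mape_upper = mape_ci$upper,
      attainment = attainment(100 * auc / t, window)
    ),
    class = "dox_evaluation"
  )
}

#' @export
print.dox_evaluation <- function(x, ...) {
  cat(sprintf("Exposure evaluation (n = %d, target %.0f ug/L*h):\n", x$n, x$target))
  cat(sprintf("  bias (MPE):       %.1f%% [%.1f, %.1f]\n", x$mpe, x$mpe_lower, x$mpe_upper))
  cat(sprintf("  precision (MAPE): %.1f%% [%.1f, %.1f]\n", x$mape, x$mape_lower, x$mape_upper))
  cat(sprintf("  attainment %g-%g%%: %.1f%%\n", x$window[1], x$window[2],
              100 * x$attainment))
  invisible(x)
}

#' Tidy an exposure evaluation
#'
#' @param x A `dox_evaluation` object.
#' @param ... Unused.
#' @return A tibble with one row per metric (`mpe`, `mape`, `attainment`)
#'   and columns `estimate`, `conf.low`, `conf.high` (confidence bounds are
#'   `NA` for attainment).
#' @exportS3Method generics::tidy
tidy.dox_evaluation <- function(x, ...) {
  tibble::tibble(
    metric = c("mpe", "mape", "attainment"),
    estimate = c(x$mpe, x$mape, 100 * x$attainment),
    conf.low = c(x$mpe_lower, x$mape_lower, NA_real_),
    conf.high = c(x$mpe_upper, x$mape_upper, NA_real_),
    unit = c("%", "%", "% of patients")
  )
}

#' Glance at an exposure evaluation
#'
#' @inheritParams tidy.dox_evaluation
#' @return A one-row tibble with `n`, `target`, `mpe`, `mape`,
#'   `attainment_pct`.
#' @exportS3Method generics::glance
glance.dox_evaluation <- function(x, ...) {
  tibble::tibble(n = x$n, target = x$target, mpe = x$mpe, mape = x$mape,
                 attainment_pct = 100 * x$attainment)
}
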