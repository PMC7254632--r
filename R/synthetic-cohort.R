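# Virtual paediatric cohorts: the package's stand-in for the (non-deposited)
# trial population, so the observed-vs-adapted evaluation runs end to end on
# synthetic data.

#' Generate a synthetic paediatric cohort
#'
#' Emulates the structure of the paediatric oncology population behind the
#' clearance model: by default 94 patients aged 2.5 months to 18 years with
#' exactly 4 infants below 1 year (the youngest pinned at 2.5 months).
#' Ages of the remaining children are drawn log-uniformly over 1--18 years
#' (infants log-uniformly over \[2.5/12, 1)); growth percentiles are uniform
#' on (2.5, 97.5) -- the skewed (L < 0) weight references do not support
#' extreme upper percentiles, mirroring the charts' published percentile
#' range. Each child's true clearance is the model prediction times
#' a lognormal individual effect, `cl_true = cl_model * exp(eta)`,
#' `eta ~ N(0, omega_cl^2)` -- the synthetic analogue of an empirical-Bayes
#' clearance estimate. Conventional (protocol-rule) and model-adapted doses
#' and their achieved AUCs are filled in for every child.
#'
#' This is an emulation of the population's stated structure, not a
#' reconstruction of the real demographics.
#'
#' @param n Cohort size (default 94).
#' @param regimen A `dox_regimen`.
#' @param variability A [variability_model()]; only `omega_cl` is used here.
#' @param seed Integer seed (required).
#' @param n_infants Number of children below 1 year (default 4; must be
#'   `<= n`).
#' @param age_min,age_max Age range in years (defaults 2.5/12 and 18).
#' @param sex_ratio Probability a child is male (default 0.5).
#' @param target Optional [reference_target()]; defaults to the regimen's
#'   standard dose at the median 18-year-old male.
#' @param coeffs A [clearance_coefficients()] object.
#' @param age_sampler Optional function `(n)` returning ages in years,
#'   replacing the default distribution (infant pinning still applies if the
#'   draws happen to contain infants; set `n_infants = NA` to disable the
#'   constraint entirely).
#' @return A tibble of cohort records: demographics, `cl_model`, `cl_true`,
#'   `dose_conventional_mg`, `dose_adapted_mg`, `auc_observed`,
#'   `auc_adapted` (ug/L*h). The target is stored in `attr(, "target")`.
#' @examples
#' cohort <- generate_cohort(regimen = load_regimen("cws_sotisar"), seed = 1)
#' summary(cohort$age)
#' @export
generate_cohort <- function(n = 94, regimen,
                            variability = variability_model(), seed,
                            n_infants = 4, age_min = 2.5 / 12, age_max = 18,
                            sex_ratio = 0.5, target = NULL,
                            coeffs = clearance_coefficients(),
                            age_sampler = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.na(n_infants) && n_infants > n) {
    stop("`n_infants` cannot exceed `n`", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(age_sampler)) {
    if (is.na(n_infants)) {
      ages <- exp(stats::runif(n, log(age_min), log(age_max)))
    } else {
      infant_ages <- c(age_min,
                       exp(stats::runif(n_infants - 1, log(age_min), log(1))))
      older_ages <- exp(stats::runif(n - n_infants, log(1), log(age_max)))
      ages <- c(infant_ages, older_ages)
    }
  } else {
    ages <- age_sampler(n)
  }
  sex <- ifelse(stats::runif(n) < sex_ratio, "male", "female")
  pct <- stats::runif(n, 2.5, 97.5)
  eta <- stats::rnorm(n, 0, variability$omega_cl)

  demo <- purrr::map2_dfr(sex, seq_len(n), function(s, i) {
    demographics_at(s, ages[i], pct[i])
  })
  dosed <- model_based_dose(demo, regimen, target = target, coeffs = coeffs)
  target <- attr(dosed, "target")
  out <- dosed |>
    dplyr::mutate(
      id = dplyr::row_number(),
      cl_true = .data$cl_model * exp(eta),
      auc_observed = auc_direct(.data$dose_conventional_mg, .data$cl_true),
      auc_adapted = auc_direct(.data$dose_adapted_mg, .data$cl_true)
    ) |>
    dplyr::select("id", dplyr::everything())
  attr(out, "target") <- target
  attr(out, "seed") <- seed
  out
}

#' Evaluate a cohort's observed versus dose-adapted exposure
#'
#' Builds one [evaluation_report()] per dosing strategy (conventional
#' protocol rules versus the model-based adaptation) against the cohort's
#' reference target, plus paired tests on the normalised AUCs (Wilcoxon
#' signed-rank) and attainment flags (McNemar).
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param target Optional target override (a [reference_target()] or a
#'   number in ug/L*h); defaults to the target stored on the cohort.
#' @param window Attainment window in percent.
#' @return A `dox_cohort_evaluation` object: list with `observed` and
#'   `adapted` `dox_evaluation`s and the paired p-values.
#' @examples
#' cohort <- generate_cohort(regimen = load_regimen("cws_sotisar"), seed = 1)
#' evaluate_cohort(cohort)
#' @export
evaluate_cohort <- function(cohort, target = NULL, window = c(80, 125)) {
  if (is.null(target)) target <- attr(cohort, "target")
  if (is.null(target)) stop("no target stored on the cohort; supply `target`", call. = FALSE)
  t <- if (inherits(target, "dox_reference_target")) target$target_auc else target
  obs <- evaluation_report(cohort$auc_observed, t, window)
  adp <- evaluation_report(cohort$auc_adapted, t, window)
  structure(
    list(
      observed = obs, adapted = adp, n = nrow(cohort), target = t,
      window = window,
      p_auc = compare_paired(cohort$auc_observed, cohort$auc_adapted,
                             "continuous"),
      p_attainment = compare_paired(
        obs$normalised_auc >= window[1] & obs$normalised_auc <= window[2],
        adp$normalised_auc >= window[1] & adp$normalised_auc <= window[2],
        "binary")
    ),
    class = "dox_cohort_evaluation"
  )
}

#' @export
print.dox_cohort_evaluation <- function(x, ...) {
  cat(sprintf("Cohort evaluation (n = %d, target %.0f ug/L*h)\n", x$n, x$target))
  cat("-- conventional protocol dosing --\n"); print(x$observed)
  cat("-- model-based adapted dosing --\n"); print(x$adapted)
  cat(sprintf("paired Wilcoxon p = %.3g; McNemar (attainment) p = %.3g\n",
              x$p_auc, x$p_attainment))
  invisible(x)
}

#' Tidy a cohort evaluation
#'
#' @param x A `dox_cohort_evaluation`.
#' @param ... Unused.
#' @return A tibble with one row per strategy x metric.
#' @exportS3Method generics::tidy
tidy.dox_cohort_evaluation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$observed), strategy = "observed"),
    dplyr::mutate(tidy(x$adapted), strategy = "adapted")
  ) |>
    dplyr::select("strategy", dplyr::everything())
}

#' Glance at a cohort evaluation
#'
#' @inheritParams tidy.dox_cohort_evaluation
#' @return A one-row tibble with both strategies' headline metrics and the
#'   paired-test p-values.
#' @exportS3Method generics::glance
glance.dox_cohort_evaluation <- function(x, ...) {
  tibble::tibble(
    n = x$n, target = x$target,
    mpe_observed = x$observed$mpe, mpe_adapted = x$adapted$mpe,
    mape_observed = x$observed$mape, mape_adapted = x$adapted$mape,
    attainment_observed_pct = 100 * x$observed$attainment,
    attainment_adapted_pct = 100 * x$adapted$attainment,
    p_auc = x$p_auc, p_attainment = x$p_attainment
  )
}
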