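# Covariate model for doxorubicin clearance and the reference exposure target.

#' Coefficients of the clearance covariate model
#'
#' The published paediatric covariate model predicts doxorubicin clearance
#' from body surface area and age:
#'
#' `CL = cl_base * (1 + (BSA - bsa_ref) * bsa_slope) * (1 + (age/age_scale)^age_exp)`
#'
#' with the defaults fixed to the published estimates. They are data, not
#' hard-coded constants, so refit values can be supplied without code change.
#'
#' @param cl_base Baseline clearance in L/h (default 9.26).
#' @param bsa_slope BSA slope per m² (default 1.30).
#' @param bsa_ref Reference BSA in m² (default 0.77).
#' @param age_scale Age scale in years (default 5.32).
#' @param age_exp Age exponent, dimensionless (default 0.286).
#' @return An object of class `dox_cl_coefficients`.
#' @export
clearance_coefficients <- function(cl_base = 9.26, bsa_slope = 1.30,
                                   bsa_ref = 0.77, age_scale = 5.32,
                                   age_exp = 0.286) {
  vals <- c(cl_base = cl_base, bsa_slope = bsa_slope, bsa_ref = bsa_ref,
            age_scale = age_scale, age_exp = age_exp)
  if (any(vals <= 0)) stop("all clearance coefficients must be positive", call. = FALSE)
  structure(as.list(vals), class = "dox_cl_coefficients")
}

#' @export
print.dox_cl_coefficients <- function(x, ...) {
  cat("Doxorubicin clearance covariate model:\n")
  cat(sprintf("  CL = %.2f * (1 + (BSA - %.2f) * %.2f) * (1 + (age/%.2f)^%.3f) L/h\n",
              x$cl_base, x$bsa_ref, x$bsa_slope, x$age_scale, x$age_exp))
  invisible(x)
}

#' Model-predicted (typical) doxorubicin clearance
#'
#' Evaluates the covariate model at a given age and body surface area.
#' At age 0 the age factor `(age/age_scale)^age_exp` is taken as its
#' continuous limit 0, so a newborn's age factor is exactly 1.
#'
#' @param age Age in years (>= 0). Vectorised.
#' @param bsa Body surface area in m². Vectorised.
#' @param coeffs A [clearance_coefficients()] object.
#' @return Clearance in L/h.
#' @examples
#' typical_clearance(0, 0.77)    # 9.26 L/h at the reference covariates
#' typical_clearance(18, 1.84)   # ~53.5 L/h for a typical 18-year-old
#' @export
typical_clearance <- function(age, bsa, coeffs = clearance_coefficients()) {
  stopifnot(inherits(coeffs, "dox_cl_coefficients"))
  if (any(age < 0)) stop("`age` must be non-negative", call. = FALSE)
  age_factor <- 1 + ifelse(age == 0, 0, (age / coeffs$age_scale)^coeffs$age_exp)
  bsa_factor <- 1 + (bsa - coeffs$bsa_ref) * coeffs$bsa_slope
  cl <- coeffs$cl_base * bsa_factor * age_factor
  if (any(cl <= 0)) {
    stop("covariates outside model support: non-positive clearance", call. = FALSE)
  }
  cl
}

#' Reference exposure target of a typical 18-year-old
#'
#' The dose-individualisation rule aims every child at the exposure a typical
#' 18-year-old (by default the median male) would attain under the regimen's
#' reference dose: `target AUC = reference dose (ug) / CL(reference)`.
#' With the published coefficients this gives 344 ug/L*h for 10 mg/m² and
#' about 1278 ug/L*h for 1 mg/kg. Because `bsa_ref * bsa_slope` is almost
#' exactly 1, the per-m² target is nearly independent of the reference BSA,
#' making it robust to the growth-chart release.
#'
#' @param basis `"per_m2"` (reference dose in mg/m²) or `"per_kg"` (mg/kg).
#' @param reference_dose Reference dose on the chosen basis.
#' @param reference_profile One-row demographics tibble for the reference
#'   individual; defaults to the median 18-year-old male from
#'   [demographics_at()].
#' @param coeffs A [clearance_coefficients()] object.
#' @return An object of class `dox_reference_target`: a list with
#'   `basis`, `reference_dose`, `reference_age`, `reference_bsa`,
#'   `reference_weight`, `cl_reference` (L/h), `dose_reference_mg`
#'   (absolute mg), and `target_auc` (ug/L*h).
#' @examples
#' reference_target("per_m2", 10)$target_auc   # ~344
#' reference_target("per_kg", 1)$target_auc    # ~1278
#' @export
reference_target <- function(basis = c("per_m2", "per_kg"), reference_dose,
                             reference_profile = NULL,
                             coeffs = clearance_coefficients()) {
  basis <- match.arg(basis)
  if (reference_dose <= 0) stop("`reference_dose` must be positive", call. = FALSE)
  if (is.null(reference_profile)) {
    reference_profile <- demographics_at("male", 18, 50)
  }
  stopifnot(nrow(reference_profile) == 1)
  cl_ref <- typical_clearance(reference_profile$age, reference_profile$bsa, coeffs)
  dose_mg <- switch(basis,
    per_m2 = reference_dose * reference_profile$bsa,
    per_kg = reference_dose * reference_profile$weight
  )
  structure(
    list(
      basis = basis,
      reference_dose = reference_dose,
      reference_age = reference_profile$age,
      reference_bsa = reference_profile$bsa,
      reference_weight = reference_profile$weight,
      cl_reference = cl_ref,
      dose_reference_mg = dose_mg,
      target_auc = auc_direct(dose_mg, cl_ref)
    ),
    class = "dox_reference_target"
  )
}

#' @export
print.dox_reference_target <- function(x, ...) {
  cat(sprintf(
    "Reference exposure target: %.0f ug/L*h\n  (%g %s, reference %s aged %g y, BSA %.2f m2, CL %.1f L/h)\n",
    x$target_auc, x$reference_dose,
    if (x$basis == "per_m2") "mg/m2" else "mg/kg",
    "individual", x$reference_age, x$reference_bsa, x$cl_reference))
  invisible(x)
}
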