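# End-to-end analyses: typical curves, variability bands, cohort evaluation.
# Each writer leaves a JSON manifest (settings, seed, package version) next
# to its outputs so a run can be reproduced exactly.

write_outputs <- function(tables, out_dir, manifest, overwrite = FALSE) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    if (file.exists(path) && !overwrite) {
      stop(sprintf("%s exists; use overwrite = TRUE", path), call. = FALSE)
    }
    readr::write_csv(tables[[nm]], path)
  }
  manifest$package_version <- as.character(utils::packageVersion("doxadapt"))
  manifest$written <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Typical exposure curves for a set of regimens
#'
#' The deterministic analysis: typical AUC and peak concentration across the
#' age range for each regimen, for a child on the given growth percentile
#' (variability set to zero).
#'
#' @param regimens A list of `dox_regimen` objects (or a single one).
#' @param sex,percentile,age_grid,coeffs As in [typical_exposure_vs_age()].
#' @param out_dir Optional output directory; one CSV per regimen plus a JSON
#'   manifest.
#' @param overwrite Overwrite existing outputs?
#' @return A tibble combining all regimens (column `regimen`).
#' @examples
#' run_typical_curves(load_regimen("cws_sotisar"),
#'                    age_grid = c(0.5, 2, 18))
#' @export
run_typical_curves <- function(regimens, sex = "male", percentile = 50,
                               age_grid = seq(0, 18, by = 1 / 12),
                               coeffs = clearance_coefficients(),
                               out_dir = NULL, overwrite = FALSE) {
  if (inherits(regimens, "dox_regimen")) regimens <- list(regimens)
  curves <- purrr::map(regimens, function(r) {
    dplyr::mutate(
      typical_exposure_vs_age(r, sex, percentile, age_grid, coeffs),
      regimen = r$name
    )
  })
  names(curves) <- paste0("typical_", purrr::map_chr(regimens, "name"))
  write_outputs(curves, out_dir,
                list(analysis = "typical_curves", sex = sex,
                     percentile = percentile,
                     regimens = purrr::map_chr(regimens, "name")),
                overwrite)
  dplyr::bind_rows(curves)
}

#' Monte-Carlo variability bands across the age range
#'
#' For each grid age, the child on the given percentile is replicated under
#' lognormal inter-individual variability on clearance and inter-individual
#' plus per-occasion variability on central volume; the 5th/50th/95th
#' percentiles of AUC and peak concentration form the bands.
#'
#' @inheritParams run_typical_curves
#' @param regimen A single `dox_regimen`.
#' @param variability A [variability_model()].
#' @param n_replicates Replicates per age (default 1000).
#' @param seed Integer seed (required); each age uses a sub-seed derived
#'   from it.
#' @return A tibble with one row per age x quantity (`auc`, `cmax`) and the
#'   percentile bands.
#' @examples
#' run_variability_bands(load_regimen("cws_sotisar"), age_grid = c(1, 2),
#'                       n_replicates = 100, seed = 42)
#' @export
run_variability_bands <- function(regimen, sex = "male", percentile = 50,
                                  age_grid = seq(0, 18, by = 0.5),
                                  variability = variability_model(),
                                  n_replicates = 1000, seed,
                                  out_dir = NULL, overwrite = FALSE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  bands <- purrr::imap_dfr(age_grid, function(a, i) {
    child <- demographics_at(sex, a, percentile)
    monte_carlo_exposure(child, regimen, variability, n_replicates,
                         seed = seed + i) |>
      dplyr::mutate(age = a)
  }) |>
    dplyr::select("age", dplyr::everything())
  write_outputs(list(variability_bands = bands), out_dir,
                list(analysis = "variability_bands", regimen = regimen$name,
                     sex = sex, percentile = percentile, seed = seed,
                     n_replicates = n_replicates,
                     omega_cl = variability$omega_cl,
                     omega_v1 = variability$omega_v1,
                     iov_v1 = variability$iov_v1),
                overwrite)
  bands
}

#' Observed-versus-adapted evaluation on a synthetic cohort
#'
#' Generates a virtual cohort, doses it both conventionally (protocol rules)
#' and with the model-based adaptation, and evaluates bias, precision and
#' 80--125% target attainment for both strategies.
#'
#' @inheritParams generate_cohort
#' @param out_dir Optional output directory (per-patient table, report JSON,
#'   manifest).
#' @param overwrite Overwrite existing outputs?
#' @param ... Passed on to [generate_cohort()].
#' @return A list with `cohort` (tibble) and `evaluation`
#'   (`dox_cohort_evaluation`).
#' @examples
#' res <- run_adaptation_evaluation(load_regimen("cws_sotisar"), seed = 1)
#' res$evaluation
#' @export
run_adaptation_evaluation <- function(regimen, n = 94,
                                      variability = variability_model(),
                                      seed, out_dir = NULL, overwrite = FALSE,
                                      ...) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  cohort <- generate_cohort(n = n, regimen = regimen,
                            variability = variability, seed = seed, ...)
  ev <- evaluate_cohort(cohort)
  if (!is.null(out_dir)) {
    write_outputs(list(cohort = cohort, evaluation = tidy(ev)), out_dir,
                  list(analysis = "adaptation_evaluation",
                       regimen = regimen$name, n = n, seed = seed,
                       omega_cl = variability$omega_cl,
                       target = ev$target),
                  overwrite)
    jsonlite::write_json(
      glance(ev), file.path(out_dir, "evaluation_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, evaluation = ev)
}
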