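# Treatment regimens and their age/weight-conditioned dose-modification rules.

#' Define a dose-modification rule
#'
#' A rule applies when all of its stated conditions hold; boundary strictness
#' is recorded explicitly because protocols differ ("< 6 months" strict,
#' ">= 6 months but <= 10 kg" inclusive).
#'
#' @param basis `"BSA"` (dose = standard_dose * BSA * fraction) or `"BW"`
#'   (dose = standard_dose / bw_conversion_divisor * weight * fraction).
#' @param fraction Fraction of the basis dose in (0, 1].
#' @param age_min,age_max Age bounds in years (optional).
#' @param age_min_inclusive,age_max_inclusive Boundary strictness; defaults:
#'   lower bound inclusive, upper bound exclusive.
#' @param weight_max Weight bound in kg (optional).
#' @param weight_max_inclusive Whether the weight bound is "<=" (TRUE) or "<".
#' @param label Human-readable description.
#' @return A `dox_dose_rule` list.
#' @export
dose_rule <- function(basis = c("BSA", "BW"), fraction = 1,
                      age_min = NULL, age_max = NULL,
                      age_min_inclusive = TRUE, age_max_inclusive = FALSE,
                      weight_max = NULL, weight_max_inclusive = FALSE,
                      label = NULL) {
  basis <- match.arg(basis)
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(age_min) && is.null(age_max) && is.null(weight_max)) {
    stop("a dose rule needs at least one age or weight condition", call. = FALSE)
  }
  structure(
    list(basis = basis, fraction = fraction,
         age_min = age_min, age_max = age_max,
         age_min_inclusive = age_min_inclusive,
         age_max_inclusive = age_max_inclusive,
         weight_max = weight_max,
         weight_max_inclusive = weight_max_inclusive,
         label = label %||% sprintf("%d%% of %s-based dose", round(fraction * 100), basis)),
    class = "dox_dose_rule"
  )
}

rule_matches <- function(rule, age, weight) {
  ok <- TRUE
  if (!is.null(rule$age_min)) {
    ok <- ok & if (rule$age_min_inclusive) age >= rule$age_min else age > rule$age_min
  }
  if (!is.null(rule$age_max)) {
    ok <- ok & if (rule$age_max_inclusive) age <= rule$age_max else age < rule$age_max
  }
  if (!is.null(rule$weight_max)) {
    ok <- ok & if (rule$weight_max_inclusive) weight <= rule$weight_max else weight < rule$weight_max
  }
  ok
}

#' Define a treatment regimen
#'
#' @param name Machine name of the regimen.
#' @param standard_dose Standard dose in mg/m².
#' @param infusion_duration Infusion duration in h.
#' @param rules Ordered list of [dose_rule()]s; the first matching rule wins
#'   and a full BSA-based dose (fraction 1) is the fallback. Ship rules
#'   youngest-first.
#' @param bw_conversion_divisor Conversion from mg/m² to mg/kg for BW-based
#'   rules, in (mg/m²)/(mg/kg); conventionally 30.
#' @param label Display name.
#' @return A `dox_regimen` object.
#' @examples
#' regimen("flat", standard_dose = 25, infusion_duration = 1)
#' @export
regimen <- function(name, standard_dose, infusion_duration,
                    rules = list(), bw_conversion_divisor = 30, label = name) {
  if (standard_dose <= 0 || infusion_duration <= 0) {
    stop("`standard_dose` and `infusion_duration` must be positive", call. = FALSE)
  }
  stopifnot(all(vapply(rules, inherits, logical(1), "dox_dose_rule")))
  structure(
    list(name = name, label = label, standard_dose = standard_dose,
         infusion_duration = infusion_duration,
         bw_conversion_divisor = bw_conversion_divisor, rules = rules),
    class = "dox_regimen"
  )
}

#' @export
print.dox_regimen <- function(x, ...) {
  cat(sprintf("<dox_regimen> %s: %g mg/m2 over %g h\n", x$label,
              x$standard_dose, x$infusion_duration))
  for (r in x$rules) cat("  - ", r$label, "\n", sep = "")
  cat("  - otherwise: 100% of BSA-based dose\n")
  invisible(x)
}

#' Read a regimen from a YAML config
#'
#' @param path Path to a YAML file with keys `name`, `standard_dose` (mg/m²),
#'   `infusion_duration` (h), optional `bw_conversion_divisor` and an ordered
#'   `rules` list mirroring [dose_rule()].
#' @return A `dox_regimen` object.
#' @export
read_regimen <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- purrr::map(cfg$rules %||% list(), function(r) {
    dose_rule(
      basis = r$basis, fraction = r$fraction,
      age_min = r$age_min, age_max = r$age_max,
      age_min_inclusive = r$age_min_inclusive %||% TRUE,
      age_max_inclusive = r$age_max_inclusive %||% FALSE,
      weight_max = r$weight_max,
      weight_max_inclusive = r$weight_max_inclusive %||% FALSE,
      label = r$label
    )
  })
  regimen(cfg$name, cfg$standard_dose, cfg$infusion_duration,
          rules = rules,
          bw_conversion_divisor = cfg$bw_conversion_divisor %||% 30,
          label = cfg$label %||% cfg$name)
}

#' Load one of the shipped regimens
#'
#' Three protocols from current paediatric practice are shipped as configs:
#' `"nb2016_n4"` (15 mg/m², 0.5 h; < 12 months or < 10 kg: 100% BW-based),
#' `"cws_sotisar"` (20 mg/m², 3 h; < 6 months: 67% BW-based; >= 6 months but
#' <= 10 kg: 100% BW-based), and `"aieop_bfm_all_2017"` (30 mg/m², 1 h;
#' < 6 months: 67% BSA-based; 6--12 months: 75% BSA-based).
#'
#' @param name Regimen name; see above.
#' @return A `dox_regimen` object.
#' @examples
#' load_regimen("cws_sotisar")
#' @export
load_regimen <- function(name = c("cws_sotisar", "nb2016_n4", "aieop_bfm_all_2017")) {
  name <- match.arg(name)
  read_regimen(system.file("extdata", "regimens", paste0(name, ".yaml"),
                           package = "doxadapt", mustWork = TRUE))
}

#' First applicable dose-modification rule for each child
#'
#' @param children A demographics tibble (see [demographics_at()]) with
#'   columns `age` and `weight`.
#' @param regimen A `dox_regimen`.
#' @return The input with columns `basis`, `fraction`, `rule` appended; the
#'   fallback full BSA-based dose is labelled `"standard BSA-based dose"`.
#' @export
applicable_rule <- function(children, regimen) {
  stopifnot(inherits(regimen, "dox_regimen"))
  n <- nrow(children)
  basis <- rep("BSA", n)
  fraction <- rep(1, n)
  label <- rep("standard BSA-based dose", n)
  unassigned <- rep(TRUE, n)
  for (r in regimen$rules) {
    hit <- unassigned & rule_matches(r, children$age, children$weight)
    basis[hit] <- r$basis
    fraction[hit] <- r$fraction
    label[hit] <- r$label
    unassigned <- unassigned & !hit
  }
  dplyr::mutate(children, basis = basis, fraction = fraction, rule = label)
}

#' Administered dose under a regimen's modification rules
#'
#' BSA-based rules give `standard_dose * bsa * fraction` mg; body-weight-based
#' rules convert the per-m² dose to a per-kg dose with the regimen's divisor
#' and give `standard_dose / divisor * weight * fraction` mg. Doses are not
#' rounded to vial sizes.
#'
#' @inheritParams applicable_rule
#' @return The input tibble with `basis`, `fraction`, `rule` and `dose_mg`
#'   appended.
#' @examples
#' compute_dose(demographics_at("male", c(0.3, 2, 17)), load_regimen("cws_sotisar"))
#' @export
compute_dose <- function(children, regimen) {
  applicable_rule(children, regimen) |>
    dplyr::mutate(
      dose_mg = dplyr::if_else(
        .data$basis == "BSA",
        regimen$standard_dose * .data$bsa * .data$fraction,
        regimen$standard_dose / regimen$bw_conversion_divisor *
          .data$weight * .data$fraction
      )
    )
}

#' Dose-versus-age profile along a growth percentile
#'
#' Evaluates the administered dose for a virtual child of the given sex and
#' growth percentile at every grid age and reports where the applicable rule
#' changes (the dose steps a clinician sees at protocol boundaries).
#'
#' @inheritParams demographics_at
#' @param regimen A `dox_regimen`.
#' @param age_grid Ages in years; default monthly from 0 to 18.
#' @return A tibble of demographics plus `dose_mg` and `rule`, with the ages
#'   at which the rule changes in `attr(, "discontinuities")`.
#' @examples
#' prof <- dose_vs_age_profile(load_regimen("cws_sotisar"))
#' attr(prof, "discontinuities")
#' @export
dose_vs_age_profile <- function(regimen, sex = "male", percentile = 50,
                                age_grid = seq(0, 18, by = 1 / 12)) {
  out <- compute_dose(demographics_at(sex, age_grid, percentile), regimen)
  n <- nrow(out)
  changed <- which(out$rule[-1] != out$rule[-n]) + 1
  # a rule-boundary crossing is a discontinuity only if the dose actually
  # jumps there: evaluate the outgoing rule at the incoming age and compare
  steps <- purrr::keep(changed, function(i) {
    dose_prev_rule <- if (out$basis[i - 1] == "BSA") {
      regimen$standard_dose * out$bsa[i] * out$fraction[i - 1]
    } else {
      regimen$standard_dose / regimen$bw_conversion_divisor *
        out$weight[i] * out$fraction[i - 1]
    }
    abs(dose_prev_rule - out$dose_mg[i]) > 1e-9 * max(out$dose_mg[i], 1)
  })
  attr(out, "discontinuities") <- out$age[steps]
  out
}
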