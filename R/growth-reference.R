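# Growth-reference lookups: LMS tables, virtual-child demographics, BSA.

the <- new.env(parent = emptyenv())

# Age (years) at which demographics switch from the WHO-style infant tables
# to the CDC-style child/adolescent tables.
GROWTH_SEAM_YEARS <- 5

#' Load a vendored LMS growth-reference table
#'
#' The package ships synthetic monthly LMS (skew/median/coefficient-of-
#' variation) tables emulating the WHO child growth standards (0--60 months)
#' and the CDC 2000 growth charts (60--216 months). They are interpolations
#' through published anchor medians, not verbatim copies of either release;
#' medians are accurate to about 1%.
#'
#' @param metric `"height"` (cm) or `"weight"` (kg).
#' @param sex `"male"` or `"female"`.
#' @param source `"who"` (0--60 months) or `"cdc"` (60--216 months).
#' @return A tibble with columns `age_months`, `L`, `M`, `S`.
#' @examples
#' growth_table("weight", "male", "who")
#' @export
growth_table <- function(metric = c("height", "weight"),
                         sex = c("male", "female"),
                         source = c("who", "cdc")) {
  metric <- match.arg(metric)
  sex <- match.arg(sex)
  source <- match.arg(source)
  key <- paste(metric, sex, source, sep = "_")
  if (is.null(the[[key]])) {
    path <- system.file("extdata", "growth",
                        sprintf("lms_%s_synthetic.csv", key),
                        package = "doxadapt", mustWork = TRUE)
    tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
    stopifnot(all(diff(tab$age_months) > 0), all(tab$M > 0), all(tab$S > 0))
    the[[key]] <- tab
  }
  the[[key]]
}

#' LMS back-transformation: percentile to measurement
#'
#' Converts a growth percentile to a measurement value using the LMS
#' parameterisation: `M * (1 + L*S*z)^(1/L)` for `L != 0` and `M * exp(S*z)`
#' for `L = 0`, where `z` is the standard-normal quantile of
#' `percentile / 100`.
#'
#' @param l Skew parameter (dimensionless). May be vectorised.
#' @param m Median (same units as the returned measurement); must be > 0.
#' @param s Coefficient of variation (dimensionless); must be > 0.
#' @param percentile Percentile in the open interval (0, 100).
#' @return Measurement value(s) in the units of `m`.
#' @examples
#' lms_quantile(1, 10, 0.1, 50)    # the median
#' lms_quantile(0, 10, 0.1, 97.7)  # ~ 10 * exp(0.2)
#' @export
lms_quantile <- function(l, m, s, percentile) {
  if (any(percentile <= 0 | percentile >= 100)) {
    stop("`percentile` must lie strictly between 0 and 100", call. = FALSE)
  }
  if (any(m <= 0) || any(s <= 0)) {
    stop("LMS parameters require M > 0 and S > 0", call. = FALSE)
  }
  z <- stats::qnorm(percentile / 100)
  base <- 1 + l * s * z
  if (any(base <= 0 & l != 0)) {
    stop("percentile outside the support of the LMS distribution (1 + L*S*z <= 0)",
         call. = FALSE)
  }
  ifelse(l == 0, m * exp(s * z), m * base^(1 / l))
}

#' LMS z-score of a measurement (inverse of [lms_quantile()])
#'
#' @inheritParams lms_quantile
#' @param x Measurement value, same units as `m`.
#' @return Standard-normal z-score(s).
#' @export
lms_zscore <- function(x, l, m, s) {
  ifelse(l == 0, log(x / m) / s, ((x / m)^l - 1) / (l * s))
}

# Interpolated LMS measurement for one metric at arbitrary ages (years).
# Linear interpolation of L, M, S between the bracketing monthly rows, then
# the percentile back-transformation. Source switches WHO -> CDC at the seam.
lms_measure_at <- function(metric, sex, age_years, percentile) {
  months <- age_years * 12
  purrr::map2_dbl(months, percentile, function(mo, p) {
    src <- if (mo < GROWTH_SEAM_YEARS * 12) "who" else "cdc"
    tab <- growth_table(metric, sex, src)
    if (mo > max(tab$age_months) + 1e-9 || mo < min(tab$age_months) - 1e-9) {
      stop(sprintf("age %.2f years is outside the growth-table range", mo / 12),
           call. = FALSE)
    }
    l <- stats::approx(tab$age_months, tab$L, xout = mo)$y
    m <- stats::approx(tab$age_months, tab$M, xout = mo)$y
    s <- stats::approx(tab$age_months, tab$S, xout = mo)$y
    lms_quantile(l, m, s, p)
  })
}

#' Body surface area from height and weight
#'
#' @param height Height in cm (> 0).
#' @param weight Weight in kg (> 0).
#' @param formula `"mosteller"` (default): `sqrt(height * weight / 3600)`;
#'   `"dubois"`: `0.007184 * height^0.725 * weight^0.425`.
#' @return BSA in m².
#' @examples
#' bsa_of(180, 72)               # sqrt(3.6)
#' bsa_of(180, 72, "dubois")
#' @export
bsa_of <- function(height, weight, formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  if (any(height <= 0) || any(weight <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  switch(formula,
    mosteller = sqrt(height * weight / 3600),
    dubois = 0.007184 * height^0.725 * weight^0.425
  )
}

#' Demographics of a virtual child on a growth percentile
#'
#' Looks up height-for-age and weight-for-age at the requested percentile
#' (height and weight percentiles are tied: a "p-th percentile child" is p-th
#' in both) and fills in body surface area. Ages below 5 years use the
#' WHO-style tables, ages from 5 years the CDC-style tables.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years, 0--18. Vectorised.
#' @param percentile Growth percentile in (0, 100); default 50. Vectorised.
#' @param bsa_formula Passed to [bsa_of()].
#' @return A tibble with columns `sex`, `age`, `percentile`, `height`,
#'   `weight`, `bsa`.
#' @examples
#' demographics_at("male", 18)
#' demographics_at("male", c(0.5, 1, 2, 5, 10, 18), percentile = 5)
#' @export
demographics_at <- function(sex = c("male", "female"), age, percentile = 50,
                            bsa_formula = c("mosteller", "dubois")) {
  sex <- match.arg(sex)
  bsa_formula <- match.arg(bsa_formula)
  if (any(age < 0 | age > 18)) {
    stop("`age` must lie in [0, 18] years", call. = FALSE)
  }
  n <- max(length(age), length(percentile))
  age <- rep_len(age, n)
  percentile <- rep_len(percentile, n)
  height <- lms_measure_at("height", sex, age, percentile)
  weight <- lms_measure_at("weight", sex, age, percentile)
  tibble::tibble(
    sex = sex,
    age = age,
    percentile = percentile,
    height = height,
    weight = weight,
    bsa = bsa_of(height, weight, bsa_formula)
  )
}

#' Age at which a percentile curve reaches a target weight
#'
#' Scans the monthly age grid and returns the smallest tabulated age (months,
#' reported in years) at which the interpolated weight-for-age meets or
#' exceeds `weight_target`. For the median boy the 10-kg threshold relevant to
#' several infant dose-modification rules is reached at 14 months.
#'
#' @inheritParams demographics_at
#' @param weight_target Target weight in kg.
#' @return Age in years (a multiple of 1/12).
#' @examples
#' age_at_weight("male", 50, 10) * 12  # months
#' @export
age_at_weight <- function(sex = c("male", "female"), percentile = 50,
                          weight_target) {
  sex <- match.arg(sex)
  months <- 0:216
  w <- lms_measure_at("weight", sex, months / 12, rep(percentile, length(months)))
  hit <- which(w >= weight_target)
  if (length(hit) == 0) {
    stop(sprintf("weight %.1f kg is not reached within 0-18 years on percentile %g",
                 weight_target, percentile), call. = FALSE)
  }
  months[hit[1]] / 12
}
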