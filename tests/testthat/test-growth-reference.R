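test_that("LMS back-transformation matches its closed forms and inverts", {
  # median for any skew
  expect_equal(lms_quantile(1, 10, 0.1, 50), 10)
  expect_equal(lms_quantile(-2, 10, 0.1, 50), 10)
  # L = 0 branch: M * exp(S * z)
  z <- qnorm(0.977)
  expect_equal(lms_quantile(0, 10, 0.1, 97.7), 10 * exp(0.1 * z))
  # round trip through the z-score inversion at assorted parameters
  cases <- expand.grid(l = c(-0.5, 0, 0.3, 1), p = c(1, 5, 50, 95, 99))
  for (i in seq_len(nrow(cases))) {
    x <- lms_quantile(cases$l[i], 9.5, 0.11, cases$p[i])
    z_back <- lms_zscore(x, cases$l[i], 9.5, 0.11)
    expect_equal(100 * pnorm(z_back), cases$p[i], tolerance = 1e-9)
  }
})

test_that("LMS rejects out-of-domain inputs", {
  expect_error(lms_quantile(1, 10, 0.1, 0), "percentile")
  expect_error(lms_quantile(1, 10, 0.1, 100), "percentile")
  expect_error(lms_quantile(1, -1, 0.1, 50), "M > 0")
  # deep lower tail outside the support when L*S is large
  expect_error(lms_quantile(2, 10, 0.5, 0.1), "support")
})

test_that("median demographics reproduce the vendored table anchors", {
  birth <- demographics_at("male", 0)
  expect_equal(birth$weight, 3.3464, tolerance = 1e-4)
  expect_equal(birth$height, 49.8842, tolerance = 1e-4)

  adult <- demographics_at("male", 18)
  expect_gt(adult$weight, 68); expect_lt(adult$weight, 69)
  expect_gt(adult$height, 176); expect_lt(adult$height, 177)
  expect_gt(adult$bsa, 1.83); expect_lt(adult$bsa, 1.84 + 0.005)

  # median percentile returns the interpolated M column exactly
  tab <- growth_table("height", "female", "who")
  expect_equal(demographics_at("female", 2, 50)$height,
               tab$M[tab$age_months == 24])
})

test_that("height and weight are monotone in percentile and age", {
  pcts <- c(5, 25, 50, 75, 95)
  for (a in c(0.5, 3, 10, 17)) {
    d <- demographics_at("male", rep(a, length(pcts)), pcts)
    expect_true(all(diff(d$height) > 0))
    expect_true(all(diff(d$weight) > 0))
  }
  # weight-for-age non-decreasing along a fixed percentile, monthly grid
  for (p in c(5, 50, 95)) {
    w <- demographics_at("male", (0:216) / 12, p)$weight
    expect_true(all(diff(w) > -1e-9))
  }
})

test_that("BSA formulas match their closed forms and agree on medians", {
  expect_equal(bsa_of(180, 72), sqrt(3.6))
  expect_equal(bsa_of(60, 60), 1)
  expect_equal(bsa_of(176.8, 68.9, "dubois"), 1.849414, tolerance = 1e-6)
  expect_error(bsa_of(-1, 50), "positive")
  # mosteller and dubois within 5% across median children aged 1-18
  d <- demographics_at("male", 1:18)
  ratio <- bsa_of(d$height, d$weight) / bsa_of(d$height, d$weight, "dubois")
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("the median boy reaches 10 kg at 14 months", {
  expect_equal(age_at_weight("male", 50, 10) * 12, 14)
  # birth-weight threshold met at age 0
  expect_equal(age_at_weight("male", 50, 3.0), 0)
  # lighter percentile reaches the threshold later
  expect_gt(age_at_weight("male", 5, 10), age_at_weight("male", 50, 10))
  expect_error(age_at_weight("male", 50, 500), "not reached")
})

test_that("demographics errors outside the supported age range", {
  expect_error(demographics_at("male", 19), "age")
  expect_error(demographics_at("male", -1), "age")
})
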