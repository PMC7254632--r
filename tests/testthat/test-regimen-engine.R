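test_that("the shipped regimen configs encode the protocol rules", {
  cws <- load_regimen("cws_sotisar")
  expect_equal(cws$standard_dose, 20)
  expect_equal(cws$infusion_duration, 3)
  expect_equal(cws$rules[[1]]$fraction, 0.67)
  expect_equal(cws$rules[[1]]$basis, "BW")
  expect_false(cws$rules[[1]]$age_max_inclusive)     # "< 6 months" strict
  expect_true(cws$rules[[2]]$weight_max_inclusive)   # "<= 10 kg" inclusive

  nb <- load_regimen("nb2016_n4")
  expect_equal(nb$standard_dose, 15)
  expect_equal(nb$infusion_duration, 0.5)
  expect_true(all(sapply(nb$rules, `[[`, "fraction") == 1))

  aieop <- load_regimen("aieop_bfm_all_2017")
  expect_equal(aieop$standard_dose, 30)
  expect_true(all(sapply(aieop$rules, `[[`, "basis") == "BSA"))
  expect_equal(sapply(aieop$rules, `[[`, "fraction"), c(0.67, 0.75))
})

test_that("rule resolution follows protocol boundaries", {
  cws <- load_regimen("cws_sotisar")
  r <- applicable_rule(demographics_at("male", c(0.3, 0.75, 17)), cws)
  expect_equal(r$basis, c("BW", "BW", "BSA"))
  expect_equal(r$fraction, c(0.67, 1, 1))

  aieop <- load_regimen("aieop_bfm_all_2017")
  r2 <- applicable_rule(demographics_at("male", c(0.3, 0.75, 1.5)), aieop)
  expect_equal(r2$fraction, c(0.67, 0.75, 1))
  expect_true(all(r2$basis == "BSA"))

  # boundary semantics: 6 months belongs to the 6-12 month band (inclusive low)
  at6mo <- applicable_rule(demographics_at("male", 0.5), aieop)
  expect_equal(at6mo$fraction, 0.75)
})

test_that("administered doses follow the basis arithmetic", {
  cws <- load_regimen("cws_sotisar")
  child <- tibble::tibble(sex = "male", age = 0.7, percentile = 50,
                          height = 70, weight = 8, bsa = bsa_of(70, 8))
  expect_equal(compute_dose(child, cws)$dose_mg, 20 / 30 * 8)
  infant <- tibble::tibble(sex = "male", age = 0.3, percentile = 50,
                           height = 60, weight = 6, bsa = bsa_of(60, 6))
  expect_equal(compute_dose(infant, cws)$dose_mg, 20 / 30 * 6 * 0.67)
  # fallback: full BSA-based dose, standard_dose mg at 1 m2
  one_m2 <- tibble::tibble(sex = "male", age = 10, percentile = 50,
                           height = 120, weight = 30, bsa = 1)
  expect_equal(compute_dose(one_m2, flat_regimen(dose = 25))$dose_mg, 25)
})

test_that("BW-based dosing undercuts BSA dosing when weight/BSA < divisor", {
  d <- demographics_at("male", seq(0.25, 1, by = 0.25))
  expect_true(all(d$weight / d$bsa < 30))
  bw_dose <- 20 / 30 * d$weight
  bsa_dose <- 20 * d$bsa
  expect_true(all(bw_dose < bsa_dose))
})

test_that("dose-vs-age profiles locate the protocol discontinuities", {
  cws_prof <- dose_vs_age_profile(load_regimen("cws_sotisar"))
  steps <- attr(cws_prof, "discontinuities")
  # 67% -> 100% BW at 6 months, BW -> BSA at the 10-kg crossing (14 months)
  expect_equal(steps, c(0.5, 14 / 12), tolerance = 1e-9)

  # within a rule's validity region dose is non-decreasing in age
  for (rl in unique(cws_prof$rule)) {
    expect_true(all(diff(cws_prof$dose_mg[cws_prof$rule == rl]) > -1e-9))
  }

  # no rules -> no discontinuities
  flat_prof <- dose_vs_age_profile(flat_regimen())
  expect_length(attr(flat_prof, "discontinuities"), 0)

  # NB regimen: single upward step where age >= 1 y and weight >= 10 kg
  nb_prof <- dose_vs_age_profile(load_regimen("nb2016_n4"))
  nb_steps <- attr(nb_prof, "discontinuities")
  expect_length(nb_steps, 1)
  expect_equal(nb_steps, 14 / 12, tolerance = 1e-9)
  at_step <- which(nb_prof$age == nb_steps)
  expect_gt(nb_prof$dose_mg[at_step], nb_prof$dose_mg[at_step - 1])
})

test_that("regimen and rule constructors validate their inputs", {
  expect_error(dose_rule("BSA", fraction = 0), "fraction")
  expect_error(dose_rule("BSA", fraction = 0.5), "condition")
  expect_error(regimen("x", standard_dose = -5, infusion_duration = 1), "positive")
})
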