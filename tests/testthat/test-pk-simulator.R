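test_that("one-compartment infusion matches the textbook closed form", {
  p <- toy_one_cmt()
  prof <- simulate_profile(p, dose = 10, infusion_duration = 1,
                           times = c(0, 0.5, 1, 3))
  # c(t) = Rate/CL * (1 - exp(-CL t / V)) in mg/L, x1000 for ug/L
  rate <- 10 / 1
  expected_during <- rate / 5 * (1 - exp(-5 * c(0, 0.5, 1) / 10)) * 1000
  expect_equal(prof$concentration[1:3], expected_during, tolerance = 1e-9)
  expect_equal(prof$concentration[3], 786.93868, tolerance = 1e-6)
  # post-infusion monoexponential decay from the end-of-infusion value
  expect_equal(prof$concentration[4],
               prof$concentration[3] * exp(-5 * 2 / 10), tolerance = 1e-9)
  expect_equal(prof$concentration[1], 0)
})

test_that("multi-compartment profiles match an independent ODE oracle", {
  set.seed(402)
  times <- c(0.25, 0.5, 1, 2, 6, 12, 24)
  for (i in 1:5) {
    params <- random_pk_params()
    closed <- simulate_profile(params, dose = 25, infusion_duration = 2,
                               times = times)$concentration
    oracle <- ode_profile_oracle(params, dose = 25, tinf = 2,
                                 times = c(0, times))[-1]
    expect_equal(closed, oracle, tolerance = 1e-4)  # <= 0.01% relative
  }
})

test_that("profile-integrated AUC equals dose/CL for random parameter sets", {
  set.seed(811)
  for (i in 1:6) {
    params <- random_pk_params()
    dose <- runif(1, 5, 80)
    # dense trapezoidal integration plus closed-form terminal tail:
    # the terminal slope equals the slowest eigenvalue of the system
    tgrid <- sort(c(seq(0, 48, by = 0.02), seq(48, 2000, by = 2)))
    prof <- simulate_profile(params, dose, infusion_duration = 1.5,
                             times = tgrid)
    trap <- sum(diff(tgrid) *
                  (head(prof$concentration, -1) + tail(prof$concentration, -1)) / 2)
    lam_slow <- max(eigen(doxadapt:::rate_matrix(params))$values)
    tail_auc <- prof$concentration[length(tgrid)] / abs(lam_slow)
    expect_equal((trap + tail_auc) / auc_direct(dose, params$cl), 1,
                 tolerance = 1e-3)
  }
})

test_that("exposure summaries obey linear-kinetics identities", {
  p <- toy_three_cmt()
  e1 <- exposure_from_profile(p, dose = 10, infusion_duration = 1)
  # AUC = dose/CL regardless of volumes and duration
  expect_equal(e1$auc, 10 * 1000 / p$cl)
  e2 <- exposure_from_profile(p, dose = 10, infusion_duration = 2)
  expect_equal(e2$auc, e1$auc)
  # cmax strictly decreases as the infusion lengthens
  expect_lt(e2$cmax, e1$cmax)
  durations <- c(0.5, 1, 2, 4, 8)
  cmaxes <- sapply(durations, function(tt)
    exposure_from_profile(p, 10, tt)$cmax)
  expect_true(all(diff(cmaxes) < 0))
  # doubling the dose doubles both AUC and cmax exactly
  e4 <- exposure_from_profile(p, dose = 20, infusion_duration = 1)
  expect_equal(e4$auc, 2 * e1$auc)
  expect_equal(e4$cmax, 2 * e1$cmax)
})

test_that("auc_direct applies the mg -> ug conversion and guards cl", {
  expect_equal(auc_direct(1, 1), 1000)
  expect_equal(auc_direct(9.356, 9.266), 1009.713, tolerance = 1e-6)
  expect_error(auc_direct(10, 0), "positive")
})

test_that("typical exposure across age peaks at the 10-kg crossing for CWS", {
  curve <- typical_exposure_vs_age(load_regimen("cws_sotisar"))
  expect_equal(curve$age[which.max(curve$auc)], 14 / 12, tolerance = 1e-9)
  # extrapolation below 2.5 months is flagged
  expect_true(all(curve$extrapolated[curve$age < 2.5 / 12]))
  expect_false(any(curve$extrapolated[curve$age >= 2.5 / 12]))
  # constant BSA dosing: AUC strictly decreasing from age 2 to 18
  flat <- typical_exposure_vs_age(flat_regimen(), age_grid = seq(2, 18, 0.5))
  expect_true(all(diff(flat$auc) < 0))
})

test_that("Monte-Carlo exposure is seeded, reproducible and collapses at zero omega", {
  child <- demographics_at("male", 2)
  cws <- load_regimen("cws_sotisar")
  no_var <- variability_model(omega_cl = 0, omega_v1 = 0, iov_v1 = 0)
  mc0 <- monte_carlo_exposure(child, cws, no_var, n_replicates = 20, seed = 5)
  typ <- typical_exposure_vs_age(cws, age_grid = 2)
  expect_equal(mc0$median[mc0$quantity == "auc"], typ$auc, tolerance = 1e-9)
  expect_equal(mc0$p05, mc0$p95, tolerance = 1e-12)

  a <- monte_carlo_exposure(child, cws, n_replicates = 100, seed = 11)
  b <- monte_carlo_exposure(child, cws, n_replicates = 100, seed = 11)
  expect_identical(a, b)
  expect_error(monte_carlo_exposure(child, cws, n_replicates = 10), "seed")
})

test_that("the Monte-Carlo AUC median sits on the typical value (lognormal)", {
  child <- demographics_at("male", 6)
  cws <- load_regimen("cws_sotisar")
  mc <- monte_carlo_exposure(child, cws,
                             variability_model(omega_cl = 0.3, omega_v1 = 0,
                                               iov_v1 = 0),
                             n_replicates = 20000, seed = 99)
  typ <- typical_exposure_vs_age(cws, age_grid = 6)
  expect_equal(mc$median[mc$quantity == "auc"] / typ$auc, 1, tolerance = 0.01)
})
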