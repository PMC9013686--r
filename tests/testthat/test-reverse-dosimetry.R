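# Plate activity computation, 4PL fitting, free-concentration equivalence,
# reverse dosimetry and curve shifting.

test_that("relative activity reproduces the control-anchored percentage", {
  expect_equal(relative_activity(0.9, 0.1, 0.9), 100)
  expect_equal(relative_activity(0.1, 0.1, 0.9), 0)
  expect_equal(relative_activity(0.5, 0.1, 0.9), 50)
  expect_error(relative_activity(0.5, 0.9, 0.2), "dynamic range")
})

test_that("4PL fit recovers the generating curve from a noiseless plate", {
  plate <- generate_ache_plate(ic50 = 1.89, hill = 1)
  act <- relative_activity(plate$delta_test, plate$delta_positive,
                           plate$delta_solvent)
  fit <- fit_concentration_response(plate$cpo_nM, act)
  expect_lt(abs(fit$ic50 - 1.89) / 1.89, 0.005)
  expect_equal(fit$top, 100, tolerance = 0.01)
  expect_equal(fit$bottom, 0, tolerance = 0.5)
  # symmetric response: IC50 equals the midpoint concentration
  conc <- c(0.1, 0.3, 1, 3, 10, 30)
  act2 <- logistic4(conc, 100, 0, 1, 1)
  fit2 <- fit_concentration_response(conc, act2)
  expect_equal(fit2$ic50, 1, tolerance = 1e-4)
  expect_error(fit_concentration_response(c(1, 2, 3, 4), c(90, 60, 30, 10)),
               "at least 5")
})

test_that("IC50 confidence interval covers the truth on noisy plates", {
  hits <- 0
  for (seed in 1:200) {
    plate <- generate_ache_plate(cv = 0.03, seed = seed)
    act <- relative_activity(plate$delta_test, plate$delta_positive,
                             plate$delta_solvent)
    fit <- try(fit_concentration_response(plate$cpo_nM, act), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.finite(fit$ic50_ci[1]) && fit$ic50_ci[1] <= 1.89 &&
        fit$ic50_ci[2] >= 1.89) hits <- hits + 1
  }
  expect_gte(hits, 180)
})

test_that("free-concentration equivalence is the stated identity", {
  part <- default_partitioning()
  expect_equal(part$fu_cpo_blood, 0.15 / 2.7, tolerance = 1e-12)
  expect_equal(in_vitro_to_blood(1, part), 18.0, tolerance = 1e-12)
  expect_equal(in_vitro_to_blood(0, part), 0)
  # fu_blood of 1 makes the translation an identity
  p1 <- default_partitioning(fu_cpo_plasma = 1, bp_cpo = 1)
  expect_equal(in_vitro_to_blood(7.3, p1), 7.3)
  # round trip blood -> in vitro -> blood
  x <- c(0.2, 1, 18, 400)
  expect_equal(in_vitro_to_blood(blood_to_in_vitro(x, part), part), x,
               tolerance = 1e-12)
})

test_that("reverse dosimetry inverts the dose-Cmax map", {
  map <- dose_to_cmax_curve(exp(seq(log(0.01), log(50), length.out = 17)))
  expect_equal(reverse_dose(0, map), 0)
  for (d0 in c(0.05, 0.47, 3, 20)) {
    cm <- simulate_pbk(d0)$cmax_cpo_free * 1000   # nM free
    expect_equal(reverse_dose(cm, map), d0, tolerance = 0.005)
  }
  expect_error(reverse_dose(1e9, map), "outside the map range")
})

test_that("reverse dosimetry preserves responses; shifts act on dose only", {
  map <- dose_to_cmax_curve(exp(seq(log(0.01), log(50), length.out = 15)))
  plate <- generate_ache_plate()
  act <- relative_activity(plate$delta_test, plate$delta_positive,
                           plate$delta_solvent)
  fit <- fit_concentration_response(plate$cpo_nM, act)
  conc <- exp(seq(log(0.01), log(5), length.out = 9))
  curve <- build_dose_response(fit, map, concentrations = conc)
  expect_equal(curve$inhibition[-1],
               sort(100 - logistic4(conc, fit$top, fit$bottom, fit$ic50,
                                    fit$hill)),
               tolerance = 1e-9)
  expect_equal(curve$inhibition[1], 0)
  expect_true(all(diff(curve$dose) > 0))
  expect_true(all(curve$inhibition >= 0 & curve$inhibition <= 100))
  s1 <- shift_curve(curve, 1)
  expect_equal(s1$dose, curve$dose)
  s2 <- shift_curve(curve, 2, population = "p99_sensitive")
  expect_equal(s2$dose, curve$dose / 2)
  expect_equal(s2$inhibition, curve$inhibition)
  expect_error(shift_curve(curve, 0))
})
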