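# Compartmental model behaviour: rate laws, mass balance, monotonicity,
# mode reductions and solver robustness.

test_that("pathway rate laws evaluate their Michaelis-Menten forms", {
  kin <- biphasic_kin_fixture()
  expect_equal(pathway1_rate(0, kin), 0)
  # at S = Km(high): half of the high-affinity Vmax plus the low-affinity term
  expect_equal(pathway1_rate(0.270, kin),
               950.4 / 2 + 1219.9 * 0.27 / 30.07, tolerance = 1e-9)
  ks <- liver_kinetics("supersome")
  expect_equal(pathway1_rate(0, ks), 0)
  expect_equal(pathway1_rate(1e9, ks), sum(ks$p1$vmax), tolerance = 1e-4)
  expect_equal(pathway_rate_mm(627.9, 1000, 627.9), 500)
  expect_equal(pathway_rate_mm(0, 1000, 627.9), 0)
  expect_equal(pathway_rate_mm(100, 37.98 * 3456, 627.9),
               37.98 * 3456 * 100 / 727.9)
})

test_that("zero dose gives an identically zero simulation", {
  r <- simulate_pbk(0)
  expect_true(all(r$amounts == 0))
  expect_equal(r$cmax_cpo_total, 0)
  expect_equal(r$cmax_cpo_free, 0)
})

test_that("mass balance holds to 0.1% at all times in every mode", {
  for (mode in c("supersome", "hlm_biphasic", "hlm_nonbiphasic")) {
    kin <- liver_kinetics(mode)
    for (dose in c(0.1, 0.47, 180)) {
      r <- simulate_pbk(dose, kin = kin)
      expect_lt(r$mass_balance_residual, 1e-3)
    }
  }
})

test_that("absorbed amount scales with fa and Cmax increases with it", {
  p1 <- default_physiology(fa = 0.231)
  p2 <- default_physiology(fa = 0.462)
  r1 <- simulate_pbk(0.5, phys = p1, kin = liver_kinetics("supersome", phys = p1))
  r2 <- simulate_pbk(0.5, phys = p2, kin = liver_kinetics("supersome", phys = p2))
  expect_equal(r2$dose_umol_absorbed, 2 * r1$dose_umol_absorbed)
  expect_gt(r2$cmax_cpo_free, r1$cmax_cpo_free)
})

test_that("with metabolism off, all CPF stays in the body and no CPO forms", {
  kin <- single_mm_kin()
  kin$p1$vmax <- 1e-12; kin$p2$vmax <- 1e-12
  r <- simulate_pbk(1, kin = kin, duration = 200)
  n <- nrow(r$amounts)
  cpf_total <- sum(r$amounts[n, 1:6])
  expect_equal(cpf_total, r$dose_umol_absorbed, tolerance = 1e-6)
  expect_lt(max(r$amounts[, "blood_cpo"]), 1e-6 * r$dose_umol_absorbed)
})

test_that("free CPO Cmax is nondecreasing in dose for every kinetic mode", {
  doses <- c(0.1, 0.5, 2, 10, 50, 200)
  for (mode in c("supersome", "hlm_biphasic", "hlm_nonbiphasic")) {
    map <- dose_to_cmax_curve(doses, kin = liver_kinetics(mode))
    expect_true(all(diff(map$cmax_free) > 0))
    expect_true(all(diff(map$cmax_total) > 0))
  }
  expect_equal(nrow(dose_to_cmax_curve(numeric(0))), 0)
})

test_that("one-isoform recombinant mode reduces to the single-MM mode", {
  kin_a <- single_mm_kin()
  kin_b <- kin_a
  kin_b$mode <- "supersome"
  r_a <- simulate_pbk(1, kin = kin_a)
  r_b <- simulate_pbk(1, kin = kin_b)
  expect_equal(r_a$cmax_cpo_free, r_b$cmax_cpo_free, tolerance = 1e-12)
})

test_that("compiled and pure-R right-hand sides agree", {
  for (mode in c("supersome", "hlm_biphasic")) {
    kin <- liver_kinetics(mode)
    rc <- simulate_pbk(0.47, kin = kin, engine = "c")
    rr <- simulate_pbk(0.47, kin = kin, engine = "r")
    expect_equal(rc$cmax_cpo_free, rr$cmax_cpo_free, tolerance = 1e-6)
    expect_equal(unname(rc$amounts[50, ]), unname(rr$amounts[50, ]),
                 tolerance = 1e-6)
  }
})

test_that("halving the solver tolerance moves free Cmax by <0.1%", {
  r1 <- simulate_pbk(0.47, rtol = 1e-8, atol = 1e-10)
  r2 <- simulate_pbk(0.47, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(r1$cmax_cpo_free - r2$cmax_cpo_free) / r2$cmax_cpo_free,
            1e-3)
})

test_that("omitting the high-affinity phase under-predicts CPO at low dose", {
  bi <- simulate_pbk(0.47, kin = liver_kinetics("hlm_biphasic"))
  nb <- simulate_pbk(0.47, kin = liver_kinetics("hlm_nonbiphasic"))
  expect_lt(nb$cmax_cpo_total, bi$cmax_cpo_total)
  # recombinant-CYP and biphasic HLM predictions are similar at low dose,
  # with the gap widening as dose increases
  ratio <- function(d) {
    a <- simulate_pbk(d, kin = liver_kinetics("supersome"))$cmax_cpo_total
    b <- simulate_pbk(d, kin = liver_kinetics("hlm_biphasic"))$cmax_cpo_total
    max(a, b) / min(a, b)
  }
  expect_lt(ratio(0.1), 1.3)
  expect_gt(ratio(20), ratio(0.1))
  expect_lt(ratio(20), 2.5)
})

test_that("sensitivity coefficients behave as the model structure dictates", {
  sc <- sensitivity_analysis(0.5, perturbation = 0.05)
  g <- function(nm) sc$sc[sc$parameter == nm]
  expect_equal(g("bp_cpf"), 0)            # does not enter the ODE
  expect_gte(abs(g("fa")), 0.1)
  expect_gte(abs(g("ka")), 0.1)
  expect_gte(abs(g("mpl")), 0.1)
  # faster detoxification (higher Vmax, lower Km) lowers the free Cmax
  expect_lt(g("p3_vmax"), 0)
  expect_gt(g("p3_km"), 0)
  expect_lt(g("p4_vmax"), 0)
  expect_gt(g("p4_km"), 0)
  expect_error(sensitivity_analysis(0.5, perturbation = 0.5))
})

test_that("urinary TCPy excretion approaches completeness by 120 h", {
  r <- simulate_pbk(0.5, duration = 120)
  expect_gt(r$urinary_tcpy_fraction, 0.9)
})
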