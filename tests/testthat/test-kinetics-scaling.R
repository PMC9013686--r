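# Michaelis-Menten fitting, ISEF computation and in-vitro to in-vivo scaling.

test_that("Michaelis-Menten fit recovers noiseless kinetics to 0.1%", {
  cases <- list(c(7.76, 0.14), c(3.96, 0.61), c(1844, 290), c(17.78, 29.77))
  for (truth in cases) {
    s <- assay_designs()$cpf_2B6
    if (truth[2] > 50) s <- assay_designs()$plasma_cpo
    v <- mm_rate(s, truth[1], truth[2])
    fit <- fit_michaelis_menten(s, v)
    expect_lt(abs(fit$vmax_app - truth[1]) / truth[1], 1e-3)
    expect_lt(abs(fit$km_app - truth[2]) / truth[2], 1e-3)
    expect_equal(fit$ce_app, fit$vmax_app / fit$km_app, tolerance = 1e-9)
  }
})

test_that("Michaelis-Menten fit recovers Vmax within 10% under 5% CV noise", {
  worst <- 0
  for (seed in 1:100) {
    d <- generate_incubation(1844, 290, assay_designs()$plasma_cpo,
                             cv = 0.05, replicates = 3, seed = seed)
    fit <- fit_michaelis_menten(d$concentration_uM, d$velocity)
    worst <- max(worst, abs(fit$vmax_app - 1844) / 1844)
  }
  expect_lt(worst, 0.10)
})

test_that("degenerate incubation data is rejected with a clear failure", {
  s <- c(1, 2, 5, 10, 20)
  expect_error(fit_michaelis_menten(s, rep(0, 5)), "zero")
  expect_error(fit_michaelis_menten(c(1, 1, 1, 2), c(1, 1, 1, 2)),
               "distinct")
  expect_error(fit_michaelis_menten(s, c(-1, 1, 2, 3, 4)), "nonnegative")
})

test_that("ISEF matches the reported values from probe Vmax pairs", {
  expect_equal(round(compute_isef(0.15, 39.06, 52), 2), 0.07)
  expect_equal(round(compute_isef(0.31, 40.77, 15.8), 2), 0.48)
  # ratio identity and the perfect-system unity
  expect_equal(compute_isef(1.0, 100, 10), 1.0)
  ab <- 52; vss <- 40
  expect_equal(compute_isef(vss * ab / 1000, vss, ab), 1.0)
  expect_error(compute_isef(0.15, 39.06, 0), "abundance")
  expect_error(compute_isef(0.15, 0, 52), "recombinant")
})

test_that("recombinant-CYP scaling reproduces whole-liver Vmax values", {
  expect_equal(scale_supersome_vmax(7.76, 15.8, 0.481, 32, 1.8), 203.94,
               tolerance = 0.005)
  expect_equal(scale_supersome_vmax(2.74, 5.4, 0.21, 32, 1.8), 10.81,
               tolerance = 0.01)
  expect_equal(scale_supersome_vmax(5, 10, 0, 32, 1.8), 0)
  expect_equal(scale_supersome_vmax(5, 0, 0.5, 32, 1.8), 0)
})

test_that("HLM and plasma scaling reproduce the whole-body values", {
  expect_equal(scale_hlm_vmax(0.353, 32, 1.8), 1219.9, tolerance = 1e-4)
  expect_equal(scale_hlm_vmax(0.353, 32, 1.8) / 29.8, 41, tolerance = 0.02)
  expect_equal(scale_hlm_vmax(0.275, 32, 1.8) / 0.270, 3520,
               tolerance = 0.001)
  expect_equal(scale_hlm_vmax(0, 32, 1.8), 0)
  expect_equal(scale_plasma_vmax(1844, 5.27), 320937, tolerance = 0.002)
  expect_equal(scale_plasma_vmax(100, 5.0), 16500)
  expect_equal(scale_plasma_vmax(1844, 0), 0)
})

test_that("unit audit: scaling at unit inputs returns the composite factor", {
  expect_equal(scale_supersome_vmax(1, 1, 1, 1, 1), 60 * 1000 / 1e6)
  expect_equal(scale_hlm_vmax(1, 1, 1), 60 * 1000 / 1000)
  expect_equal(scale_plasma_vmax(1, 1), 60 * 1000 * 0.55 / 1000)
})

test_that("scaled CE is invariant to trading Vmax against ISEF", {
  iso <- supersome_kinetics()
  base <- summed_scaled_ce(iso, 1, 32, 1.8)
  iso2 <- iso
  cc <- 3.7
  iso2$vmax1 <- iso2$vmax1 * cc
  expect_equal(summed_scaled_ce(iso2, 1, 32, 1.8, isef = iso$isef / cc),
               base, tolerance = 1e-12)
})

test_that("summed scaled catalytic efficiencies match the whole-liver totals", {
  iso <- supersome_kinetics()
  expect_equal(summed_scaled_ce(iso, 1, 32, 1.8), 1578, tolerance = 0.02)
  one <- iso[2, ]
  sp <- scaled_pathway(one, 1, 32, 1.8)
  expect_equal(summed_scaled_ce(one, 1, 32, 1.8), sp$ce_invivo)
  # pathway 2 lacks the extreme affinity split of pathway 1: the low-Km to
  # high-Km CE contrast is ~50-fold for bioactivation but <3-fold for
  # detoxification, and the summed recombinant-CYP CE is comparable
  # (~1.4-fold) to the pooled-HLM CE for that reaction
  contrast <- function(pw) {
    p <- scaled_pathway(iso, pw, 32, 1.8)
    sum(p$ce_invivo[p$km < 10]) / sum(p$ce_invivo[p$km >= 10])
  }
  expect_gt(contrast(1), 30)
  expect_lt(contrast(2), 3)
  ce_hlm_p2 <- scale_hlm_vmax(0.653, 32, 1.8) / 12
  expect_equal(summed_scaled_ce(iso, 2, 32, 1.8) / ce_hlm_p2, 1.4,
               tolerance = 0.05)
})

test_that("Eadie-Hofstee diagnostic separates mono- from biphasic kinetics", {
  s <- exp(seq(log(0.05), log(100), length.out = 30))
  expect_false(eadie_hofstee_diagnostic(s, mm_rate(s, 5, 1))$biphasic)
  mix <- mm_rate(s, 1, 0.14) + mm_rate(s, 1, 29.8)
  expect_true(eadie_hofstee_diagnostic(s, mix)$biphasic)
  iso <- supersome_kinetics()
  v_of <- function(pw) {
    p <- scaled_pathway(iso, pw, 32, 1.8)
    rowSums(sapply(1:4, function(j) mm_rate(s, p$vmax_invivo[j], p$km[j])))
  }
  expect_true(eadie_hofstee_diagnostic(s, v_of(1))$biphasic)
  expect_false(eadie_hofstee_diagnostic(s, v_of(2))$biphasic)
})

test_that("mm_params enforces positivity and the CE identity", {
  p <- mm_params(7.76, 0.14)
  expect_equal(p$ce_app, 7.76 / 0.14, tolerance = 1e-12)
  expect_error(mm_params(-1, 0.14))
  expect_error(mm_params(1, 0))
})
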