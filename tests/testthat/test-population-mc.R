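# Truncated-lognormal sampling, phenotype mixtures, weighted statistics and
# the population Monte Carlo simulation.

test_that("lognormal specification matches the log-space transformation", {
  sp <- lognormal_spec(52, 0.67)
  expect_equal(sp$sigma_w^2, log(1 + 0.67^2), tolerance = 1e-12)
  expect_equal(sp$mu_w, log(52 / sqrt(1 + 0.67^2)), tolerance = 1e-12)
  expect_equal(sp$sigma_w, 0.60894, tolerance = 1e-4)
  expect_equal(sp$mu_w, 3.76584, tolerance = 1e-4)
  expect_equal(sp$lower, sp$mu_w - 3 * sp$sigma_w)
  expect_equal(sp$upper, sp$mu_w + 3 * sp$sigma_w)
  # a hard cap tightens the upper bound only
  spf <- lognormal_spec(0.46, 0.73, cap = 1)
  expect_equal(spf$upper, log(1))
  expect_lt(spf$upper, spf$mu_w + 3 * spf$sigma_w)
  # zero CV collapses to the mean
  sp0 <- lognormal_spec(10, 0)
  expect_equal(sp0$sigma_w, 0)
  expect_equal(sample_lognormal(sp0, 7)$values, rep(10, 7))
})

test_that("sampling recovers mean and CV and discards tail draws", {
  set.seed(42)
  sp <- lognormal_spec(52, 0.67)
  out <- sample_lognormal(sp, 1e5)
  x <- out$values
  expect_lt(abs(mean(x) - 52) / 52, 0.02)
  # CV against the exact truncated-lognormal moments (the +-3 sigma cut
  # shrinks the CV by a few percent relative to the untruncated 0.67)
  tmom <- function(k, mu, s) {
    exp(k * mu + k^2 * s^2 / 2) *
      (pnorm(3 - k * s) - pnorm(-3 - k * s)) / (pnorm(3) - pnorm(-3))
  }
  cv_true <- sqrt(tmom(2, sp$mu_w, sp$sigma_w) /
                    tmom(1, sp$mu_w, sp$sigma_w)^2 - 1)
  expect_lt(abs(sd(x) / mean(x) - cv_true) / cv_true, 0.03)
  # acceptance close to the two-sided 3-sigma normal mass
  expect_lt(abs(out$accepted / out$n - 0.9973), 0.002)
  expect_true(all(log(x) >= sp$lower & log(x) <= sp$upper))
})

test_that("phenotype combinations enumerate with product weights", {
  combos <- enumerate_phenotype_combinations()
  expect_equal(nrow(combos), 6)
  expect_equal(sum(combos$weight), 1, tolerance = 1e-9)
  emem <- combos$weight[combos$`2B6` == "EM" & combos$`2C19` == "EM"]
  expect_equal(emem, 0.890 * 0.590, tolerance = 1e-12)
  single <- data.frame(cyp = c("1A2", "3A4"), phenotype = c("EM", "EM"),
                       abundance = c(52, 137), cv = c(0.67, 0.41),
                       frequency = c(1, 1))
  c1 <- enumerate_phenotype_combinations(single)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$weight, 1)
  bad <- single; bad$frequency <- c(0.8, 1)
  expect_error(enumerate_phenotype_combinations(bad), "sum")
})

test_that("weighted quantile and GM honor ordering and closed forms", {
  set.seed(7)
  for (i in 1:20) {
    x <- exp(rnorm(500, 0, runif(1, 0.1, 1)))
    w <- runif(500)
    q <- weighted_quantile(x, w, c(0.01, 0.95, 0.99))
    gm <- weighted_gm(x, w)
    expect_true(q[1] <= gm && gm <= q[2] && q[2] <= q[3])
  }
  # equal weights agree with the unweighted quantile to sampling resolution
  x <- exp(rnorm(2e4, 0, 0.6))
  q95 <- weighted_quantile(x, rep(1, length(x)), 0.95)
  expect_equal(q95, unname(quantile(x, 0.95, type = 5)), tolerance = 1e-3)
  # pure lognormal through an identity model: P95/GM = exp(1.645 sigma)
  expect_equal(q95 / weighted_gm(x, rep(1, length(x))),
               exp(qnorm(0.95) * 0.6), tolerance = 0.05)
  expect_lte(weighted_quantile(x, rep(1, length(x)), 0.5, type = "nearest"),
             weighted_quantile(x, rep(1, length(x)), 0.500001))
})

test_that("degenerate population (all CVs zero) gives HKAF exactly 1", {
  # one phenotype per CYP and zero CVs: every accepted run is identical
  pheno0 <- phenotype_table()
  pheno0 <- pheno0[pheno0$phenotype == "EM", ]
  pheno0$cv <- 0
  pheno0$frequency <- 1
  hlm0 <- hlm_kinetics()
  for (nm in names(hlm0)) hlm0[[nm]]$cv_vmax <- hlm0[[nm]]$cv_km <- 0
  r <- run_population("supersome", "kinetic_only", dose = 0.47,
                      n_per_combo = 10, seed = 3, hlm = hlm0,
                      pheno = pheno0)
  expect_equal(r$hk_af_95, 1, tolerance = 1e-9)
  expect_equal(r$hk_af_99, 1, tolerance = 1e-9)
  expect_equal(r$accepted_runs, r$total_runs)
})

test_that("population runs are seed-reproducible and properly weighted", {
  a <- run_population("supersome", "kinetic_only", n_per_combo = 40,
                      seed = 11)
  b <- run_population("supersome", "kinetic_only", n_per_combo = 40,
                      seed = 11)
  expect_identical(a$cmax, b$cmax)
  expect_identical(a$gm, b$gm)
  expect_equal(sum(a$weights), 1, tolerance = 1e-9)
  expect_true(a$p1 <= a$gm && a$gm <= a$p95 && a$p95 <= a$p99)
  expect_gte(a$hk_af_95, 1)
  expect_lte(a$accepted_runs, a$total_runs)
  expect_equal(hk_af(a, 99), a$hk_af_99)
  expect_equal(hk_af(a, 95), a$hk_af_95)
})

test_that("adding influential-parameter variability raises the HKAF", {
  kin <- run_population("supersome", "kinetic_only", n_per_combo = 150,
                        seed = 5)
  all <- run_population("supersome", "all_influential", n_per_combo = 150,
                        seed = 5)
  expect_lt(kin$hk_af_99, all$hk_af_99)
  expect_lt(kin$hk_af_95, all$hk_af_95)
  # run-level rejection removes more draws when more parameters are sampled
  expect_lt(all$accepted_runs, kin$accepted_runs)
})

test_that("blood:plasma ratio correlates positively with the free fraction", {
  expect_equal(bp_cpo_from_fu(0.15), 2.7, tolerance = 1e-12)
  fu <- c(0.05, 0.15, 0.45)
  bp <- bp_cpo_from_fu(fu)
  expect_true(all(diff(bp) > 0))
  # free blood fraction fu/BP still increases with fu (sublinearly)
  expect_true(all(diff(fu / bp) > 0))
})
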