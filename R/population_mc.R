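# Truncated-lognormal Monte Carlo simulation of inter-individual
# variability, CYP phenotype mixtures, and the chemical-specific adjustment
# factor HKAF = high percentile / geometric mean of the free blood CPO Cmax.

#' Truncated lognormal distribution specification
#'
#' Converts an arithmetic mean and coefficient of variation into the
#' parameters of the underlying normal distribution in log space,
#' `sigma_w^2 = ln(1 + CV^2)`, `mu_w = ln(mu / sqrt(1 + CV^2))`, with
#' truncation bounds at `mu_w +/- 3 sigma_w` and an optional hard upper cap
#' (e.g. a fraction absorbed of at most 1) applied as an additional upper
#' truncation bound.
#'
#' @param mu_x arithmetic mean (> 0)
#' @param cv_x coefficient of variation (>= 0)
#' @param cap optional upper cap on the natural scale
#' @return Object of class `dist_spec` with fields `mu_x`, `cv_x`, `mu_w`,
#'   `sigma_w`, `lower`, `upper` (log-space bounds).
#' @export
lognormal_spec <- function(mu_x, cv_x, cap = NA_real_) {
  stopifnot(mu_x > 0, cv_x >= 0)
  sigma_w <- sqrt(log(1 + cv_x^2))
  mu_w <- log(mu_x / sqrt(1 + cv_x^2))
  upper <- mu_w + 3 * sigma_w
  if (is.finite(cap)) upper <- min(upper, log(cap))
  structure(list(mu_x = mu_x, cv_x = cv_x, mu_w = mu_w, sigma_w = sigma_w,
                 lower = mu_w - 3 * sigma_w, upper = upper),
            class = "dist_spec")
}

#' Sample a truncated lognormal specification
#'
#' Draws `exp(Normal(mu_w, sigma_w))`; draws outside the truncation bounds
#' are discarded (neither clipped nor replaced), so fewer than `n` values may
#' be returned. With `cv_x = 0` all `n` draws equal the mean.
#'
#' @param spec `dist_spec`
#' @param n number of attempted draws
#' @return list with `values` (accepted draws on the natural scale),
#'   `accepted` (count) and `n`.
#' @export
sample_lognormal <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), n > 0)
  if (spec$sigma_w == 0)
    return(list(values = rep(spec$mu_x, n), accepted = n, n = n))
  w <- rnorm(n, spec$mu_w, spec$sigma_w)
  ok <- w >= spec$lower & w <= spec$upper
  list(values = exp(w[ok]), accepted = sum(ok), n = n)
}

# Draw the log-space normals for one spec without applying the truncation,
# returning values and the per-draw acceptance mask (run-level rejection is
# applied jointly over all sampled parameters).
.draw_masked <- function(spec, n) {
  if (spec$sigma_w == 0)
    return(list(x = rep(spec$mu_x, n), ok = rep(TRUE, n)))
  w <- rnorm(n, spec$mu_w, spec$sigma_w)
  list(x = exp(w), ok = w >= spec$lower & w <= spec$upper)
}

#' Enumerate CYP phenotype combinations
#'
#' Cartesian product of the phenotypes of each CYP, weighted by the product
#' of the per-CYP phenotype frequencies. CYPs with a single phenotype do not
#' multiply the combination count.
#'
#' @param tab [phenotype_table()]-style data.frame
#' @return data.frame with one row per combination: one column per CYP
#'   holding the phenotype label, plus `weight`. Weights sum to 1 when every
#'   CYP's frequencies sum to 1.
#' @export
enumerate_phenotype_combinations <- function(tab = phenotype_table()) {
  cyps <- unique(tab$cyp)
  per <- lapply(cyps, function(cc) which(tab$cyp == cc))
  for (cc in cyps) {
    f <- sum(tab$frequency[tab$cyp == cc])
    if (abs(f - 1) > 1e-9)
      stop("phenotype frequencies of CYP", cc, " sum to ", f)
  }
  grid <- expand.grid(per, KEEP.OUT.ATTRS = FALSE)
  combos <- data.frame(matrix(NA_character_, nrow(grid), length(cyps)),
                       stringsAsFactors = FALSE)
  names(combos) <- cyps
  weight <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rows <- as.integer(grid[i, ])
    combos[i, ] <- tab$phenotype[rows]
    weight[i] <- prod(tab$frequency[rows])
  }
  combos$weight <- weight
  attr(combos, "row_index") <- grid
  combos
}

#' Weighted quantile
#'
#' Inverse of the weighted empirical CDF. The default (`"interpolate"`) puts
#' each sorted observation at cumulative probability
#' `(cumsum(w) - w/2) / sum(w)` and interpolates linearly;
#' `"nearest"` returns the smallest observation whose cumulative weight
#' reaches the target probability.
#'
#' @param x numeric sample
#' @param w nonnegative weights
#' @param probs probabilities in (0, 1)
#' @param type `"interpolate"` or `"nearest"`
#' @return quantile value(s)
#' @export
weighted_quantile <- function(x, w, probs,
                              type = c("interpolate", "nearest")) {
  type <- match.arg(type)
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(probs > 0 & probs < 1))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  if (type == "nearest")
    return(vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1)))
  pp <- (cumsum(w) - w / 2) / sum(w)
  vapply(probs, function(p)
    approx(pp, x, xout = p, rule = 2, ties = "ordered")$y, numeric(1))
}

#' Weighted geometric mean
#'
#' @param x strictly positive sample
#' @param w nonnegative weights
#' @return `exp(sum(w log x) / sum(w))`
#' @export
weighted_gm <- function(x, w) {
  stopifnot(all(x > 0))
  exp(sum(w * log(x)) / sum(w))
}

# One Monte Carlo block: sample the in-scope parameters, apply run-level
# rejection, solve the PBK model per accepted draw, return free Cmax values.
.mc_block <- function(n, mode, scope, dose, phys, part, hlm, isoforms,
                      pheno = phenotype_table(), pheno_rows = NULL,
                      duration = 48, rtol = 1e-7, atol = 1e-9) {
  draws <- list(); masks <- list()
  add <- function(name, spec) {
    d <- .draw_masked(spec, n)
    draws[[name]] <<- d$x
    masks[[name]] <<- d$ok
  }
  if (mode == "supersome") {
    for (j in seq_along(pheno_rows)) {
      r <- pheno[pheno_rows[j], ]
      nm <- paste0("ab_", r$cyp)
      if (r$abundance == 0 && r$cv == 0) {
        draws[[nm]] <- rep(0, n); masks[[nm]] <- rep(TRUE, n)
      } else add(nm, lognormal_spec(r$abundance, r$cv))
    }
  } else {
    add("p1h_vmax", lognormal_spec(hlm$p1_high$vmax, hlm$p1_high$cv_vmax))
    add("p1h_km", lognormal_spec(hlm$p1_high$km, hlm$p1_high$cv_km))
    add("p1l_vmax", lognormal_spec(hlm$p1_low$vmax, hlm$p1_low$cv_vmax))
    add("p1l_km", lognormal_spec(hlm$p1_low$km, hlm$p1_low$cv_km))
    add("p2_vmax", lognormal_spec(hlm$p2$vmax, hlm$p2$cv_vmax))
    add("p2_km", lognormal_spec(hlm$p2$km, hlm$p2$cv_km))
  }
  add("p3_vmax", lognormal_spec(hlm$p3$vmax, hlm$p3$cv_vmax))
  add("p3_km", lognormal_spec(hlm$p3$km, hlm$p3$cv_km))
  add("p4_vmax", lognormal_spec(hlm$p4$vmax, hlm$p4$cv_vmax))
  add("p4_km", lognormal_spec(hlm$p4$km, hlm$p4$cv_km))
  if (scope == "all_influential") {
    inf <- influential_parameter_table()
    for (i in seq_len(nrow(inf)))
      add(inf$parameter[i],
          lognormal_spec(inf$mean[i], inf$cv[i], cap = inf$cap[i]))
  }
  keep <- Reduce(`&`, masks)
  idx <- which(keep)
  mw <- molecular_weights()
  cmax <- numeric(length(idx))
  failed <- 0L
  for (k in seq_along(idx)) {
    i <- idx[k]
    ph <- phys; pa <- part
    if (scope == "all_influential") {
      ph$bw <- draws$bw[i]; ph$ka <- draws$ka[i]; ph$fa <- draws$fa[i]
      ph$mpl <- draws$mpl[i]
      pa$fu_cpo_plasma <- draws$fu_cpo_plasma[i]
      pa$bp_cpo <- bp_cpo_from_fu(pa$fu_cpo_plasma)
      pa$fu_cpo_blood <- pa$fu_cpo_plasma / pa$bp_cpo
    }
    d <- physiology_derived(ph)
    if (mode == "supersome") {
      ab <- vapply(paste0("ab_", isoforms$cyp),
                   function(nm) draws[[nm]][i], numeric(1))
      p1 <- data.frame(
        vmax = scale_supersome_vmax(isoforms$vmax1, ab, isoforms$isef,
                                    ph$mpl, d$vl),
        km = isoforms$km1)
      p2 <- data.frame(
        vmax = scale_supersome_vmax(isoforms$vmax2, ab, isoforms$isef,
                                    ph$mpl, d$vl),
        km = isoforms$km2)
    } else {
      p1 <- data.frame(
        vmax = c(scale_hlm_vmax(draws$p1h_vmax[i], ph$mpl, d$vl),
                 scale_hlm_vmax(draws$p1l_vmax[i], ph$mpl, d$vl)),
        km = c(draws$p1h_km[i], draws$p1l_km[i]))
      p2 <- data.frame(vmax = scale_hlm_vmax(draws$p2_vmax[i], ph$mpl, d$vl),
                       km = draws$p2_km[i])
    }
    kin <- structure(list(
      mode = mode, p1 = p1, p2 = p2,
      p3 = list(vmax = scale_hlm_vmax(draws$p3_vmax[i], ph$mpl, d$vl),
                km = draws$p3_km[i]),
      p4 = list(vmax = scale_plasma_vmax(draws$p4_vmax[i], d$vb),
                km = draws$p4_km[i])
    ), class = "liver_kinetics")
    parms <- .pbk_parms(ph, pa, kin)
    agi0 <- ph$fa * dose * ph$bw * 1000 / mw[["cpf"]]
    res <- try({
      out <- .pbk_solve(parms, agi0, .pbk_times(duration), rtol, atol, "c")
      .refine_cmax(parms, out, "blood_cpo", rtol, atol, "c") / d$vb *
        pa$fu_cpo_blood
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      cmax[k] <- NA_real_; failed <- failed + 1L
    } else cmax[k] <- res
  }
  list(cmax = cmax[!is.na(cmax)], attempted = n,
       accepted = length(idx) - failed, solver_failures = failed)
}

#' Monte Carlo population simulation and HKAF
#'
#' Runs the PBK model over a population sample of the kinetic (and
#' optionally all influential) parameters. In `"supersome"` mode the CYP
#' phenotype combinations are enumerated, each run `n_per_combo` times with
#' its own RNG substream, and the resulting free-Cmax distributions are
#' pooled with the combination frequencies as weights (each accepted draw
#' carries weight `frequency / n_accepted` of its combination). Draws with
#' any parameter outside its truncation bounds are discarded without
#' replacement, so accepted totals fall below the nominal count.
#'
#' `scope = "kinetic_only"` samples the CYP abundances (or HLM Vmax/Km) and
#' the pathway 3/4 kinetics; `"all_influential"` additionally samples body
#' weight (propagated to the BW-covariant volumes and flows), ka, fa (capped
#' at 1), MPL and the CPO plasma free fraction with the blood:plasma ratio
#' tied to the free-fraction draw.
#'
#' @param mode `"supersome"` or `"hlm_biphasic"`
#' @param scope `"kinetic_only"` or `"all_influential"`
#' @param dose oral CPF dose (mg/kg bw), > 0
#' @param n_per_combo draws attempted per phenotype combination
#' @param seed integer seed; combination `i` uses `seed * 100 + i`
#' @param phys,part baseline parameter objects
#' @param hlm,isoforms kinetic input tables
#' @param pheno phenotype table ([phenotype_table()]) used in
#'   `"supersome"` mode
#' @param duration simulated time per run (h)
#' @return Object of class `variability_result`: `cmax` (free Cmax draws,
#'   uM), `weights`, `gm`, `p1`, `p95`, `p99`, `hk_af_95`, `hk_af_99`,
#'   `ratio_p1` (P1/GM), `accepted_runs`, `total_runs`, `solver_failures`,
#'   `combinations`.
#' @export
run_population <- function(mode = c("supersome", "hlm_biphasic"),
                           scope = c("kinetic_only", "all_influential"),
                           dose = 0.47, n_per_combo = 2000, seed = 1,
                           phys = default_physiology(),
                           part = default_partitioning(),
                           hlm = hlm_kinetics(),
                           isoforms = supersome_kinetics(),
                           pheno = phenotype_table(),
                           duration = 48) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  stopifnot(dose > 0, n_per_combo >= 10)
  if (mode == "supersome") {
    combos <- enumerate_phenotype_combinations(pheno)
    row_index <- attr(combos, "row_index")
  } else {
    combos <- data.frame(weight = 1)
    row_index <- NULL
  }
  cmax <- numeric(0); weights <- numeric(0)
  accepted <- 0L; failures <- 0L
  for (i in seq_len(nrow(combos))) {
    set.seed(seed * 100 + i)
    blk <- .mc_block(n_per_combo, mode, scope, dose, phys, part, hlm,
                     isoforms, pheno = pheno,
                     pheno_rows = if (!is.null(row_index))
                       as.integer(row_index[i, ]) else NULL,
                     duration = duration)
    if (length(blk$cmax) == 0) next
    cmax <- c(cmax, blk$cmax)
    weights <- c(weights, rep(combos$weight[i] / length(blk$cmax),
                              length(blk$cmax)))
    accepted <- accepted + blk$accepted
    failures <- failures + blk$solver_failures
  }
  if (any(cmax <= 0)) stop("nonpositive Cmax encountered")
  gm <- weighted_gm(cmax, weights)
  q <- weighted_quantile(cmax, weights, c(0.01, 0.95, 0.99))
  structure(list(
    mode = mode, scope = scope, dose = dose,
    cmax = cmax, weights = weights,
    gm = gm, p1 = q[1], p95 = q[2], p99 = q[3],
    hk_af_95 = q[2] / gm, hk_af_99 = q[3] / gm, ratio_p1 = q[1] / gm,
    accepted_runs = accepted,
    total_runs = n_per_combo * nrow(combos),
    solver_failures = failures,
    combinations = combos
  ), class = "variability_result")
}

#' @export
print.variability_result <- function(x, ...) {
  cat(sprintf("Population simulation (%s, %s) at %.3g mg/kg bw\n",
              x$mode, x$scope, x$dose))
  cat(sprintf("  accepted %d of %d runs (%d solver failures)\n",
              x$accepted_runs, x$total_runs, x$solver_failures))
  cat(sprintf("  GM %.4g uM; P1 %.4g; P95 %.4g; P99 %.4g\n",
              x$gm, x$p1, x$p95, x$p99))
  cat(sprintf("  HKAF(95) = %.2f; HKAF(99) = %.2f; P1/GM = %.2f\n",
              x$hk_af_95, x$hk_af_99, x$ratio_p1))
  invisible(x)
}

#' Chemical-specific adjustment factor from a population result
#'
#' Ratio of a high percentile of the free blood CPO Cmax distribution to its
#' geometric mean.
#'
#' @param result `variability_result`
#' @param percentile 95 or 99
#' @return dimensionless HKAF
#' @export
hk_af <- function(result, percentile = c(99, 95)) {
  percentile <- match.arg(as.character(percentile[1]), c("99", "95"))
  if (percentile == "99") result$hk_af_99 else result$hk_af_95
}
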