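# In vitro AChE inhibition -> in vivo dose-response translation:
# plate-absorbance activity computation, 4-parameter logistic fitting,
# free-concentration equivalence, and dose-axis shifts for sensitive and
# insensitive percentiles.

#' Remaining AChE activity from plate absorbance changes
#'
#' `activity% = 100 * (test - positive) / (solvent - positive)`, where each
#' term is the change in 412 nm absorbance over the 10 min kinetic read. The
#' solvent control defines 100% activity and the fully inhibited positive
#' control 0%.
#'
#' @param delta_test absorbance change of the test well(s)
#' @param delta_positive absorbance change of the positive (fully inhibited)
#'   control
#' @param delta_solvent absorbance change of the solvent control
#' @return remaining activity (%)
#' @export
relative_activity <- function(delta_test, delta_positive, delta_solvent) {
  if (any(delta_solvent - delta_positive <= 0))
    stop("no dynamic range: solvent control must exceed positive control")
  100 * (delta_test - delta_positive) / (delta_solvent - delta_positive)
}

#' Four-parameter logistic activity model
#'
#' `activity(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)`; with
#' `hill > 0` activity decreases with concentration.
#'
#' @param conc concentration(s), same units as `ic50`
#' @param top,bottom upper and lower activity asymptotes (%)
#' @param ic50 half-maximal inhibitory concentration
#' @param hill Hill slope (> 0 for inhibition)
#' @return activity (%)
#' @export
logistic4 <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a concentration-response curve (log-concentration 4PL)
#'
#' Least-squares fit of [logistic4()] with the IC50 parameterised on the log
#' scale; the 95% confidence interval of the IC50 comes from the standard
#' error of log IC50.
#'
#' @param concentrations inhibitor concentrations (nM), at least 5 spanning
#'   the transition
#' @param activities remaining activities (%)
#' @return Object of class `cr_fit`: `top`, `bottom`, `ic50` (nM), `hill`,
#'   `ic50_ci` (length-2), `rss`.
#' @export
fit_concentration_response <- function(concentrations, activities) {
  conc <- as.numeric(concentrations); act <- as.numeric(activities)
  stopifnot(length(conc) == length(act), all(conc > 0))
  if (length(unique(conc)) < 5)
    stop("need at least 5 concentrations spanning the transition")
  mid <- (max(act) + min(act)) / 2
  start <- list(top = max(act), bottom = min(act),
                lic = log10(conc[which.min(abs(act - mid))]), hill = 1)
  fit <- try(minpack.lm::nlsLM(
    act ~ bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - lic))),
    start = start,
    lower = c(top = -Inf, bottom = -Inf, lic = log10(min(conc)) - 3,
              hill = 0.1),
    upper = c(top = Inf, bottom = Inf, lic = log10(max(conc)) + 3,
              hill = 20),
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("concentration-response fit failed to converge")
  cf <- coef(fit)
  if (cf["bottom"] >= cf["top"])
    stop("concentration-response fit failed: bottom >= top")
  se_lic <- tryCatch(sqrt(diag(vcov(fit)))["lic"],
                     error = function(e) NA_real_)
  ic50 <- 10^unname(cf["lic"])
  ci <- if (is.finite(se_lic))
    10^(unname(cf["lic"]) + c(-1, 1) * 1.96 * se_lic) else c(NA, NA)
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 ic50 = ic50, hill = unname(cf["hill"]), ic50_ci = ci,
                 rss = sum(residuals(fit)^2)),
            class = "cr_fit")
}

#' @export
print.cr_fit <- function(x, ...) {
  cat(sprintf("4PL fit: IC50 = %.3g nM (95%% CI %.3g-%.3g), hill = %.3g, top = %.3g%%, bottom = %.3g%%\n",
              x$ic50, x$ic50_ci[1], x$ic50_ci[2], x$hill, x$top, x$bottom))
  invisible(x)
}

#' Free-concentration equivalence: in vitro to total blood concentration
#'
#' The in vitro effective (free) concentration is set equal to the in vivo
#' free blood concentration:
#' `C_total_blood = C_in_vitro * fu_in_vitro / fu_blood`, with
#' `fu_blood = fu_plasma / BP`. By default the in vitro free fraction is 1
#' (only trace albumin is present in the assay medium).
#'
#' @param c_in_vitro in vitro concentration(s) (nM)
#' @param part [default_partitioning()]
#' @param fu_in_vitro in vitro unbound fraction
#' @return total blood concentration(s) (nM)
#' @export
in_vitro_to_blood <- function(c_in_vitro, part = default_partitioning(),
                              fu_in_vitro = 1) {
  stopifnot(fu_in_vitro > 0, fu_in_vitro <= 1, all(c_in_vitro >= 0))
  c_in_vitro * fu_in_vitro / part$fu_cpo_blood
}

#' Blood to in vitro concentration (inverse of [in_vitro_to_blood()])
#'
#' @param c_blood total blood concentration(s) (nM)
#' @inheritParams in_vitro_to_blood
#' @return in vitro-equivalent concentration(s) (nM)
#' @export
blood_to_in_vitro <- function(c_blood, part = default_partitioning(),
                              fu_in_vitro = 1) {
  c_blood * part$fu_cpo_blood / fu_in_vitro
}

#' Reverse dosimetry: external dose matching a free blood Cmax
#'
#' Inverse interpolation (log-log, monotone) of a [dose_to_cmax_curve()] map
#' at the free blood concentration equivalent to the in vitro concentration
#' (`c_free = c_in_vitro * fu_in_vitro`, nM, converted to uM).
#'
#' @param c_in_vitro in vitro CPO concentration(s) (nM)
#' @param map `dose_cmax_map` from [dose_to_cmax_curve()]
#' @param fu_in_vitro in vitro unbound fraction
#' @return external dose(s) (mg/kg bw)
#' @export
reverse_dose <- function(c_in_vitro, map, fu_in_vitro = 1) {
  stopifnot(inherits(map, "dose_cmax_map"), all(c_in_vitro >= 0))
  target <- c_in_vitro * fu_in_vitro / 1000   # nM -> uM, free
  lo <- min(map$cmax_free); hi <- max(map$cmax_free)
  out <- numeric(length(target))
  for (i in seq_along(target)) {
    tg <- target[i]
    if (tg == 0) { out[i] <- 0; next }
    if (tg < lo || tg > hi)
      stop(sprintf(
        "target free Cmax %.4g uM outside the map range [%.4g, %.4g] (doses %.4g-%.4g mg/kg)",
        tg, lo, hi, min(map$dose), max(map$dose)))
    out[i] <- exp(approx(log(map$cmax_free), log(map$dose), xout = log(tg),
                         ties = "ordered")$y)
  }
  out
}

#' Construct an in vivo dose-response curve by reverse dosimetry
#'
#' Maps each in vitro concentration of a fitted (or supplied) inhibition
#' curve to the external dose producing the equivalent free blood Cmax, and
#' pairs it with the predicted AChE inhibition (`100 - activity`). Response
#' values are preserved exactly; only the dose axis is computed. A zero-dose
#' point with zero inhibition anchors the background.
#'
#' @param fit `cr_fit` describing the in vitro curve
#' @param map `dose_cmax_map`
#' @param concentrations in vitro concentration grid (nM); default
#'   log-spaced over the range the map covers
#' @param n_points grid size when `concentrations` is NULL
#' @param fu_in_vitro in vitro unbound fraction
#' @param population curve label
#' @return data.frame of class `dose_response_curve`: `dose` (mg/kg bw),
#'   `inhibition` (%), `population`.
#' @export
build_dose_response <- function(fit, map, concentrations = NULL,
                                n_points = 25, fu_in_vitro = 1,
                                population = "average") {
  stopifnot(inherits(fit, "cr_fit"), n_points >= 5)
  if (is.null(concentrations)) {
    rng <- range(map$cmax_free[map$cmax_free > 0]) * 1000 / fu_in_vitro
    concentrations <- exp(seq(log(rng[1] * 1.001), log(rng[2] * 0.999),
                              length.out = n_points))
  }
  act <- logistic4(concentrations, fit$top, fit$bottom, fit$ic50, fit$hill)
  doses <- reverse_dose(concentrations, map, fu_in_vitro)
  out <- data.frame(dose = c(0, doses),
                    inhibition = c(0, pmin(pmax(100 - act, 0), 100)),
                    population = population, stringsAsFactors = FALSE)
  out <- out[order(out$dose), ]
  rownames(out) <- NULL
  structure(out, class = c("dose_response_curve", "data.frame"))
}

#' Shift a dose-response curve along the dose axis
#'
#' Divides every dose by `factor`, leaving responses untouched: applying the
#' HKAF (P99/GM) yields the curve of the sensitive 99th-percentile
#' individuals; applying P1/GM (< 1) yields the insensitive 1st-percentile
#' curve.
#'
#' @param curve `dose_response_curve`
#' @param factor positive dose divisor
#' @param population new curve label
#' @return shifted `dose_response_curve`
#' @export
shift_curve <- function(curve, factor, population = NULL) {
  stopifnot(inherits(curve, "dose_response_curve"), factor > 0)
  out <- curve
  out$dose <- curve$dose / factor
  if (!is.null(population)) out$population <- population
  structure(out, class = c("dose_response_curve", "data.frame"))
}
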