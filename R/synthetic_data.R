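# Synthetic-data generators: incubation velocity datasets, an
# individual-plasma kinetics panel, and 96-well AChE inhibition plates.
# Every generator is a deterministic function of its seed, and each one is
# paired with the fitter that consumes its output, so noiseless round trips
# are exact to solver tolerance.

#' Design concentrations used in the incubation and plate assays
#'
#' @return Named list of concentration vectors: per-CYP CPF designs (uM),
#'   the plasma CPO design (uM) and the AChE plate CPO design (nM).
#' @export
assay_designs <- function() {
  list(
    cpf_1A2 = c(0.05, 0.1, 0.25, 0.5, 1, 5, 10),
    cpf_2B6 = c(0.05, 0.1, 0.25, 0.5, 1, 5, 10, 25),
    cpf_2C19 = c(1, 2.5, 5, 10, 25, 50),
    cpf_3A4 = c(0.5, 1, 2.5, 5, 10, 25, 50),
    plasma_cpo = c(10, 50, 100, 250, 500, 1000),
    ache_cpo_nM = c(0.05, 0.1, 0.5, 1, 2.5, 5, 10, 25, 50)
  )
}

# Multiplicative lognormal observation noise with observation CV `cv`.
.obs_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Generate a synthetic incubation velocity dataset
#'
#' Velocities follow `v = Vmax*S/(Km+S) * exp(eps)` with multiplicative
#' lognormal noise of observation CV `cv`, for `replicates` replicates at
#' each design concentration.
#'
#' @param vmax,km generating Michaelis-Menten truth (units free / uM)
#' @param concentrations design concentrations (uM)
#' @param cv observation coefficient of variation (default 5%)
#' @param replicates replicates per concentration (default 2)
#' @param seed integer seed
#' @param units tag recorded in the output
#' @return data.frame `concentration_uM`, `replicate`, `velocity` with the
#'   generating truth in attributes `vmax`, `km`.
#' @export
generate_incubation <- function(vmax, km,
                                concentrations = assay_designs()$cpf_2B6,
                                cv = 0.05, replicates = 2, seed = 1,
                                units = "unspecified") {
  stopifnot(vmax > 0, km > 0, cv >= 0, replicates >= 1,
            all(concentrations > 0), !is.unsorted(concentrations))
  set.seed(seed)
  s <- rep(concentrations, each = replicates)
  v <- mm_rate(s, vmax, km) * .obs_noise(length(s), cv)
  out <- data.frame(concentration_uM = s,
                    replicate = rep(seq_len(replicates),
                                    length(concentrations)),
                    velocity = v, velocity_units = units,
                    stringsAsFactors = FALSE)
  attr(out, "vmax") <- vmax
  attr(out, "km") <- km
  out
}

#' Generate an individual-plasma CPO hydrolysis panel
#'
#' Draws per-individual (Vmax, Km) from truncated lognormal population
#' distributions (independent draws; individuals falling outside the
#' truncation bounds are redrawn so the panel always has `n` members),
#' generates an incubation dataset per individual, refits each one, and
#' summarises the fitted panel.
#'
#' @param n number of individuals (>= 2)
#' @param vmax_mean,vmax_cv population truth for Vmax (nmol/min/ml plasma)
#' @param km_mean,km_cv population truth for Km (uM)
#' @param concentrations CPO design concentrations (uM)
#' @param cv observation CV of the incubation noise
#' @param replicates replicates per concentration
#' @param seed integer seed
#' @return list with `individuals` (data.frame `id`, `vmax_true`, `km_true`,
#'   `vmax_fit`, `km_fit`, `ce_fit`), `data` (stacked incubation data with
#'   `id`), and `summary` (fitted panel mean/CV of Vmax and Km and the
#'   max/min fitted CE ratio).
#' @export
generate_plasma_panel <- function(n = 25, vmax_mean = 1844, vmax_cv = 0.29,
                                  km_mean = 290, km_cv = 0.33,
                                  concentrations = assay_designs()$plasma_cpo,
                                  cv = 0.05, replicates = 2, seed = 1) {
  stopifnot(n >= 2)
  set.seed(seed)
  vspec <- lognormal_spec(vmax_mean, vmax_cv)
  kspec <- lognormal_spec(km_mean, km_cv)
  draw_n <- function(spec) {
    out <- numeric(0)
    while (length(out) < n)
      out <- c(out, sample_lognormal(spec, 2 * n)$values)
    out[seq_len(n)]
  }
  vmax_true <- draw_n(vspec)
  km_true <- draw_n(kspec)
  data_list <- vector("list", n)
  fits <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    d <- generate_incubation(vmax_true[i], km_true[i], concentrations,
                             cv = cv, replicates = replicates,
                             seed = seed * 1000 + i,
                             units = "nmol/min/ml plasma")
    d$id <- i
    data_list[[i]] <- d
    f <- fit_michaelis_menten(d$concentration_uM, d$velocity,
                              units = "nmol/min/ml plasma")
    fits[i, ] <- c(f$vmax_app, f$km_app)
  }
  individuals <- data.frame(id = seq_len(n), vmax_true = vmax_true,
                            km_true = km_true, vmax_fit = fits[, 1],
                            km_fit = fits[, 2],
                            ce_fit = fits[, 1] / fits[, 2])
  list(
    individuals = individuals,
    data = do.call(rbind, data_list),
    summary = list(
      vmax_mean = mean(fits[, 1]), vmax_cv = sd(fits[, 1]) / mean(fits[, 1]),
      km_mean = mean(fits[, 2]), km_cv = sd(fits[, 2]) / mean(fits[, 2]),
      ce_fold_range = max(individuals$ce_fit) / min(individuals$ce_fit)
    )
  )
}

#' Generate a synthetic 96-well AChE inhibition plate
#'
#' Constructs absorbance changes such that [relative_activity()] recovers
#' the 4PL activity curve: the solvent control change is `delta_solvent`,
#' the positive control `delta_positive`, and each test well
#' `positive + activity/100 * (solvent - positive)`, all subject to
#' multiplicative lognormal noise of CV `cv`.
#'
#' @param ic50 generating IC50 (nM)
#' @param hill generating Hill slope
#' @param top,bottom generating activity asymptotes (%)
#' @param concentrations CPO concentrations (nM)
#' @param delta_solvent,delta_positive noiseless control absorbance changes
#'   (AU over 10 min)
#' @param cv observation CV on each absorbance change
#' @param seed integer seed
#' @return data.frame `cpo_nM`, `delta_test`, `delta_positive`,
#'   `delta_solvent` (per-well control readings), with generator truth in
#'   attributes.
#' @export
generate_ache_plate <- function(ic50 = 1.89, hill = 1, top = 100, bottom = 0,
                                concentrations = assay_designs()$ache_cpo_nM,
                                delta_solvent = 0.9, delta_positive = 0.05,
                                cv = 0, seed = 1) {
  stopifnot(ic50 > 0, hill > 0, delta_solvent > delta_positive,
            all(concentrations > 0))
  set.seed(seed)
  act <- logistic4(concentrations, top, bottom, ic50, hill)
  nw <- length(concentrations)
  test <- (delta_positive + act / 100 * (delta_solvent - delta_positive)) *
    .obs_noise(nw, cv)
  out <- data.frame(
    cpo_nM = concentrations,
    delta_test = test,
    delta_positive = delta_positive * .obs_noise(nw, cv),
    delta_solvent = delta_solvent * .obs_noise(nw, cv)
  )
  attr(out, "ic50") <- ic50
  attr(out, "hill") <- hill
  out
}
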