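# Pipeline assembly: fit -> scale -> PBK -> Monte Carlo -> HKAF -> reverse
# dosimetry -> BMD, plus small evaluation metrics.

#' Fold difference between two positive values
#'
#' Reports both the symmetric convention `max(a, b) / min(a, b)` (always
#' >= 1) and the signed ratio `predicted / observed`.
#'
#' @param predicted,observed positive values
#' @return named vector `fold` (symmetric) and `ratio` (predicted/observed)
#' @export
fold_difference <- function(predicted, observed) {
  stopifnot(predicted > 0, observed > 0)
  c(fold = max(predicted, observed) / min(predicted, observed),
    ratio = predicted / observed)
}

#' Ingested dose from a product volume and concentration
#'
#' `dose = volume (ml) * concentration (g/l) / body weight (kg)` in mg/kg bw
#' (1 ml of a 1 g/l product carries 1 mg).
#'
#' @param volume_ml ingested volume (ml)
#' @param conc_g_per_l product concentration (g active substance per litre)
#' @param bw_kg body weight (kg)
#' @return dose (mg/kg bw)
#' @export
estimate_ingested_dose <- function(volume_ml, conc_g_per_l, bw_kg) {
  stopifnot(volume_ml >= 0, conc_g_per_l > 0, bw_kg > 0)
  volume_ml * conc_g_per_l / bw_kg
}

#' Run the full analysis pipeline
#'
#' Executes, for one kinetic approach: the in vitro concentration-response
#' fit (on a synthetic plate generated from the configured truth), the
#' kinetic scaling, the dose-to-Cmax PBK map, the Monte Carlo population
#' simulation with HKAF computation, reverse dosimetry to average /
#' sensitive (P99) / insensitive (P1) dose-response curves, and the
#' benchmark-dose analysis of the average curve.
#'
#' @param approach `"supersome"` or `"hlm_biphasic"`
#' @param scope Monte Carlo scope (`"kinetic_only"` or `"all_influential"`)
#' @param mc_dose dose for the HKAF computation (mg/kg bw)
#' @param n_per_combo Monte Carlo draws per phenotype combination
#' @param seed integer seed controlling every random element
#' @param dose_grid doses for the PBK dose-Cmax map (mg/kg bw)
#' @param plate_cv observation CV of the synthetic plate
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` and the curves/tables as CSV files
#' @return list of class `pipeline_report` with elements `config`,
#'   `in_vitro` (4PL fit), `kinetics` (scaled tables), `map`, `population`
#'   (`variability_result`), `curves` (average/p99/p1), `bmd`
#'   (`bmd_result`), `provenance` (seed and config hash).
#' @export
run_pipeline <- function(approach = c("supersome", "hlm_biphasic"),
                         scope = c("kinetic_only", "all_influential"),
                         mc_dose = 0.47, n_per_combo = 200, seed = 1,
                         dose_grid = exp(seq(log(0.001), log(200),
                                             length.out = 25)),
                         plate_cv = 0, out_dir = NULL) {
  approach <- match.arg(approach)
  scope <- match.arg(scope)
  config <- list(approach = approach, scope = scope, mc_dose = mc_dose,
                 n_per_combo = n_per_combo, seed = seed,
                 dose_grid = dose_grid, plate_cv = plate_cv)
  phys <- default_physiology()
  part <- default_partitioning()

  plate <- generate_ache_plate(cv = plate_cv, seed = seed)
  act <- relative_activity(plate$delta_test, plate$delta_positive,
                           plate$delta_solvent)
  in_vitro <- fit_concentration_response(plate$cpo_nM, act)

  kin <- liver_kinetics(approach, phys = phys)
  map <- dose_to_cmax_curve(dose_grid, phys, part, kin)

  population <- run_population(approach, scope, dose = mc_dose,
                               n_per_combo = n_per_combo, seed = seed,
                               phys = phys, part = part)

  avg <- build_dose_response(in_vitro, map)
  p99 <- shift_curve(avg, population$hk_af_99, "p99_sensitive")
  p1 <- shift_curve(avg, population$ratio_p1, "p1_insensitive")
  bmd <- bmd_analysis(avg)

  report <- structure(list(
    config = config,
    in_vitro = in_vitro,
    kinetics = if (approach == "supersome")
      export_kinetics_table(mpl = phys$mpl,
                            vl = physiology_derived(phys)$vl) else
      liver_kinetics(approach, phys = phys),
    map = map,
    population = population,
    curves = list(average = avg, p99_sensitive = p99, p1_insensitive = p1),
    bmd = bmd,
    provenance = list(seed = seed, config_hash = .config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("cpfvar")))
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    summary <- list(
      config = config[setdiff(names(config), "dose_grid")],
      ic50_nM = in_vitro$ic50,
      gm_cmax_free_uM = population$gm,
      p95 = population$p95, p99 = population$p99,
      hk_af_95 = population$hk_af_95, hk_af_99 = population$hk_af_99,
      accepted_runs = population$accepted_runs,
      total_runs = population$total_runs,
      bmd10 = bmd$bmd10, bmdl10 = bmd$bmdl10,
      best_bmd_model = bmd$best$model,
      provenance = report$provenance
    )
    jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(map, file.path(out_dir, "dose_cmax_map.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, report$curves),
              file.path(out_dir, "dose_response_curves.csv"),
              row.names = FALSE)
    write.csv(data.frame(cmax_free = population$cmax,
                         weight = population$weights),
              file.path(out_dir, "population_cmax.csv"), row.names = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline (%s, %s): IC50 %.3g nM; HKAF95 %.2f; HKAF99 %.2f; BMDL10 %.3g mg/kg bw\n",
              x$config$approach, x$config$scope, x$in_vitro$ic50,
              x$population$hk_af_95, x$population$hk_af_99, x$bmd$bmdl10))
  invisible(x)
}

# Deterministic hash of the configuration for provenance (md5 of its
# serialised form).
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Read an incubation dataset from CSV
#'
#' Expected columns: `enzyme_source`, `pathway`, `concentration_uM`,
#' `velocity`, `velocity_units`, `replicate` (extra columns pass through).
#'
#' @param path CSV file path
#' @return data.frame
#' @export
read_incubation_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_uM", "velocity")
  if (!all(need %in% names(d)))
    stop("missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d
}
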