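# PBK model of CPF absorption, distribution, bioactivation/detoxification
# and CPO/TCPy disposition. The ODE right-hand side is compiled (src/); a
# pure-R twin of the same equations is kept for cross-checking.

#' Whole-body liver/plasma kinetic description for the PBK model
#'
#' Builds the in vivo rate-law specification for the four metabolic pathways:
#' 1 CPF -> CPO (hepatic CYPs), 2 CPF -> TCPy (hepatic CYPs),
#' 3 CPO -> TCPy (hepatic PON1), 4 CPO -> TCPy (plasma PON1).
#' Apparent in vitro constants are scaled to whole-body values
#' ([scale_supersome_vmax()], [scale_hlm_vmax()], [scale_plasma_vmax()])
#' using the liver and blood sizes implied by `phys`.
#'
#' @param mode `"supersome"` (per-isoform sum, via ISEFs), `"hlm_biphasic"`
#'   (high- plus low-affinity phase for pathway 1) or `"hlm_nonbiphasic"`
#'   (low-affinity phase only; retained as a negative control since it
#'   under-estimates metabolism at low concentrations)
#' @param phys [default_physiology()]-style object
#' @param isoforms recombinant-CYP kinetics table ([supersome_kinetics()])
#' @param hlm pooled-HLM/plasma kinetics ([hlm_kinetics()])
#' @param abundance optional abundance vector overriding the table (same
#'   order as `isoforms`; entries may be 0 for null phenotypes)
#' @param isef optional ISEF vector overriding the table
#' @return Object of class `liver_kinetics`: lists `p1`, `p2` (data.frames
#'   `vmax` (umol/h), `km` (uM), up to 4 rows), `p3`, `p4` (single Vmax/Km),
#'   plus the `mode`.
#' @export
liver_kinetics <- function(mode = c("supersome", "hlm_biphasic",
                                    "hlm_nonbiphasic"),
                           phys = default_physiology(),
                           isoforms = supersome_kinetics(),
                           hlm = hlm_kinetics(),
                           abundance = NULL, isef = NULL) {
  mode <- match.arg(mode)
  d <- physiology_derived(phys)
  vl <- d$vl; vb <- d$vb; mpl <- phys$mpl
  if (mode == "supersome") {
    iso <- isoforms
    if (!is.null(abundance)) iso$abundance <- abundance
    p1 <- scaled_pathway(iso, 1, mpl, vl, isef)
    p2 <- scaled_pathway(iso, 2, mpl, vl, isef)
    p1 <- data.frame(vmax = p1$vmax_invivo, km = p1$km)
    p2 <- data.frame(vmax = p2$vmax_invivo, km = p2$km)
  } else if (mode == "hlm_biphasic") {
    p1 <- data.frame(
      vmax = c(scale_hlm_vmax(hlm$p1_high$vmax, mpl, vl),
               scale_hlm_vmax(hlm$p1_low$vmax, mpl, vl)),
      km = c(hlm$p1_high$km, hlm$p1_low$km))
    p2 <- data.frame(vmax = scale_hlm_vmax(hlm$p2$vmax, mpl, vl),
                     km = hlm$p2$km)
  } else {
    p1 <- data.frame(vmax = scale_hlm_vmax(hlm$p1_low$vmax, mpl, vl),
                     km = hlm$p1_low$km)
    p2 <- data.frame(vmax = scale_hlm_vmax(hlm$p2$vmax, mpl, vl),
                     km = hlm$p2$km)
  }
  structure(list(
    mode = mode,
    p1 = p1, p2 = p2,
    p3 = list(vmax = scale_hlm_vmax(hlm$p3$vmax, mpl, vl), km = hlm$p3$km),
    p4 = list(vmax = scale_plasma_vmax(hlm$p4$vmax, vb), km = hlm$p4$km)
  ), class = "liver_kinetics")
}

#' Pathway-1 metabolic rate at a given CPF concentration
#'
#' Sum of the Michaelis-Menten terms configured for pathway 1 (one term per
#' isoform in recombinant-CYP mode, high- plus low-affinity in biphasic mode,
#' a single term otherwise).
#'
#' @param s CPF concentration (uM), >= 0
#' @param kin `liver_kinetics`
#' @return rate (umol/h)
#' @export
pathway1_rate <- function(s, kin) {
  stopifnot(all(s >= 0))
  rowSums(outer(s, seq_len(nrow(kin$p1)),
                function(si, j) mm_rate(si, kin$p1$vmax[j], kin$p1$km[j])))
}

#' Single Michaelis-Menten pathway rate
#'
#' @param s substrate concentration (uM), >= 0
#' @param vmax in vivo maximum velocity (umol/h)
#' @param km Michaelis constant (uM)
#' @return rate (umol/h)
#' @export
pathway_rate_mm <- function(s, vmax, km) {
  stopifnot(all(s >= 0), vmax >= 0, km > 0)
  mm_rate(s, vmax, km)
}

# Fixed-length (4) Vmax/Km slots for the compiled rhs; unused slots have
# vmax 0 and km 1.
.pad4 <- function(df) {
  v <- rep(0, 4); k <- rep(1, 4)
  n <- nrow(df)
  stopifnot(n >= 1, n <= 4)
  v[seq_len(n)] <- df$vmax
  k[seq_len(n)] <- df$km
  list(vmax = v, km = k)
}

# Assemble the numeric parameter vector consumed by the compiled rhs.
.pbk_parms <- function(phys, part, kin, p4_on_free = FALSE) {
  d <- physiology_derived(phys)
  p1 <- .pad4(kin$p1); p2 <- .pad4(kin$p2)
  c(phys$ka,
    d$vl, d$vb, d$vf, d$vr, d$vs,
    d$ql, d$qf, d$qr, d$qs,
    part$pl_cpf, part$pf_cpf, part$pr_cpf, part$ps_cpf,
    part$pl_cpo, part$px_cpo,
    d$vf + d$vr + d$vs,          # CPO rest volume
    d$qf + d$qr + d$qs,          # CPO rest flow
    p1$vmax, p1$km, p2$vmax, p2$km,
    kin$p3$vmax, kin$p3$km,
    kin$p4$vmax, kin$p4$km,
    as.numeric(p4_on_free), part$fu_cpo_blood,
    phys$ke_tcpy)
}

# Pure-R right-hand side: the independent twin of src/pbk_ode.c, used by the
# cross-check tests.
.pbk_rhs_r <- function(t, y, p) {
  cb <- y[3] / p[3]
  cvl <- y[2] / (p[2] * p[11]); cvf <- y[4] / (p[4] * p[12])
  cvr <- y[5] / (p[5] * p[13]); cvs <- y[6] / (p[6] * p[14])
  cbo <- y[8] / p[3]
  cvlo <- y[7] / (p[2] * p[15]); cvxo <- y[9] / (p[17] * p[16])
  s1 <- max(cvl, 0)
  v1 <- sum(p[19:22] * s1 / (p[23:26] + s1))
  v2 <- sum(p[27:30] * s1 / (p[31:34] + s1))
  s3 <- max(cvlo, 0)
  v3 <- p[35] * s3 / (p[36] + s3)
  s4 <- max(cbo, 0) * if (p[39] > 0.5) p[40] else 1
  v4 <- p[37] * s4 / (p[38] + s4)
  ql <- p[7]; qf <- p[8]; qr <- p[9]; qs <- p[10]; qx <- p[18]
  list(c(
    -p[1] * y[1],
    ql * (cb - cvl) + p[1] * y[1] - v1 - v2,
    ql * cvl + qf * cvf + qr * cvr + qs * cvs - (ql + qf + qr + qs) * cb,
    qf * (cb - cvf),
    qr * (cb - cvr),
    qs * (cb - cvs),
    ql * (cbo - cvlo) + v1 - v3,
    ql * cvlo + qx * cvxo - (ql + qx) * cbo - v4,
    qx * (cbo - cvxo),
    v2 + v3 + v4 - p[41] * y[10],
    p[41] * y[10]
  ))
}

.state_names <- c("gut_cpf", "liver_cpf", "blood_cpf", "fat_cpf",
                  "richly_cpf", "slowly_cpf", "liver_cpo", "blood_cpo",
                  "rest_cpo", "tcpy_body", "tcpy_urine")

.pbk_solve <- function(parms, agi0, times, rtol = 1e-8, atol = 1e-10,
                       engine = c("c", "r")) {
  engine <- match.arg(engine)
  y0 <- setNames(c(agi0, rep(0, 10)), .state_names)
  if (engine == "c") {
    out <- deSolve::ode(y = y0, times = times, func = "pbk_deriv",
                        parms = parms, dllname = "cpfvar",
                        initfunc = "pbk_init", rtol = rtol, atol = atol)
  } else {
    out <- deSolve::ode(y = y0, times = times, func = .pbk_rhs_r,
                        parms = parms, rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0)
    stop("PBK ODE integration failed (istate = ", attr(out, "istate")[1], ")")
  out
}

# Output time grid: dense over the absorption/Cmax window, coarser later.
.pbk_times <- function(duration) {
  sort(unique(c(seq(0, min(12, duration), length.out = 121),
                seq(0, duration, length.out = 97))))
}

# Locate the maximum of a solved concentration series and refine it with a
# second integration over the bracketing interval.
.refine_cmax <- function(parms, out, col, rtol, atol, engine) {
  conc <- out[, col]
  i <- which.max(conc)
  if (i == 1 || i == nrow(out)) return(max(conc))
  t0 <- out[i - 1, "time"]; t1 <- out[i + 1, "time"]
  y0 <- out[i - 1, .state_names]
  fine <- deSolve::ode(
    y = y0, times = seq(t0, t1, length.out = 61),
    func = if (engine == "c") "pbk_deriv" else .pbk_rhs_r,
    parms = parms,
    dllname = if (engine == "c") "cpfvar" else NULL,
    initfunc = if (engine == "c") "pbk_init" else NULL,
    rtol = rtol, atol = atol)
  max(fine[, col])
}

#' Simulate the PBK model for a single oral CPF dose
#'
#' Integrates the compartmental model with a stiff-capable adaptive solver
#' and reports amount and concentration profiles, the maximum total and free
#' blood CPO concentrations (refined on a dense grid around the maximum),
#' the maximum blood CPF and TCPy-related outputs, and the mass-balance
#' residual.
#'
#' @param dose oral CPF dose (mg/kg body weight), >= 0
#' @param phys physiology ([default_physiology()])
#' @param part partitioning ([default_partitioning()])
#' @param kin kinetic description ([liver_kinetics()])
#' @param duration simulated time (h)
#' @param p4_on_free if `TRUE`, plasma PON1 acts on the free rather than the
#'   total blood CPO concentration
#' @param rtol,atol solver tolerances
#' @param engine `"c"` (compiled rhs) or `"r"` (pure-R twin)
#' @return Object of class `pbk_result`: `time` (h), `amounts` (umol,
#'   matrix), `conc` (data.frame of blood CPF/CPO in uM), `cmax_cpo_total`,
#'   `cmax_cpo_free`, `cmax_cpf` (uM), `auc_cpf` (uM h, trapezoid),
#'   `urinary_tcpy_fraction` (of absorbed dose at `duration`),
#'   `mass_balance_residual` (max relative deviation), `dose_umol_absorbed`.
#' @export
simulate_pbk <- function(dose, phys = default_physiology(),
                         part = default_partitioning(),
                         kin = liver_kinetics("supersome", phys = phys),
                         duration = 48, p4_on_free = FALSE,
                         rtol = 1e-8, atol = 1e-10, engine = c("c", "r")) {
  engine <- match.arg(engine)
  stopifnot(dose >= 0, duration > 0)
  mw <- molecular_weights()
  dose_umol <- dose * phys$bw * 1000 / mw["cpf"]   # mg -> umol
  agi0 <- unname(phys$fa * dose_umol)
  parms <- .pbk_parms(phys, part, kin, p4_on_free)
  out <- .pbk_solve(parms, agi0, .pbk_times(duration), rtol, atol, engine)

  d <- physiology_derived(phys)
  amounts <- out[, .state_names, drop = FALSE]
  conc <- data.frame(
    time = out[, "time"],
    cpf_blood = amounts[, "blood_cpf"] / d$vb,
    cpo_blood = amounts[, "blood_cpo"] / d$vb
  )
  total <- rowSums(amounts)
  mb <- if (agi0 > 0) max(abs(total - agi0)) / agi0 else 0

  cmax_total <- if (agi0 > 0)
    .refine_cmax(parms, out, "blood_cpo", rtol, atol, engine) / d$vb else 0
  cmax_cpf <- if (agi0 > 0)
    .refine_cmax(parms, out, "blood_cpf", rtol, atol, engine) / d$vb else 0
  auc_cpf <- sum(diff(conc$time) *
                 (head(conc$cpf_blood, -1) + tail(conc$cpf_blood, -1)) / 2)

  structure(list(
    time = conc$time, amounts = amounts, conc = conc,
    cmax_cpo_total = cmax_total,
    cmax_cpo_free = cmax_total * part$fu_cpo_blood,
    cmax_cpf = cmax_cpf,
    auc_cpf = auc_cpf,
    urinary_tcpy_fraction = if (agi0 > 0)
      unname(amounts[nrow(amounts), "tcpy_urine"] / agi0) else 0,
    mass_balance_residual = mb,
    dose_umol_absorbed = agi0
  ), class = "pbk_result")
}

#' @export
print.pbk_result <- function(x, ...) {
  cat(sprintf("PBK simulation: Cmax CPO total %.4g uM (free %.4g uM), Cmax CPF %.4g uM\n",
              x$cmax_cpo_total, x$cmax_cpo_free, x$cmax_cpf))
  cat(sprintf("  mass-balance residual %.2e, urinary TCPy fraction %.3f\n",
              x$mass_balance_residual, x$urinary_tcpy_fraction))
  invisible(x)
}

#' Dose to free-CPO-Cmax mapping
#'
#' Simulates a sorted dose grid and tabulates the maximum total and free
#' blood CPO concentrations, verifying monotonicity in dose. The map is the
#' input of reverse dosimetry ([reverse_dose()]).
#'
#' @param doses oral CPF doses (mg/kg bw), sorted nondecreasing, >= 0
#' @inheritParams simulate_pbk
#' @return data.frame of class `dose_cmax_map`: `dose`, `cmax_total`,
#'   `cmax_free` (uM).
#' @export
dose_to_cmax_curve <- function(doses, phys = default_physiology(),
                               part = default_partitioning(),
                               kin = liver_kinetics("supersome", phys = phys),
                               duration = 48, ...) {
  if (length(doses) == 0)
    return(structure(data.frame(dose = numeric(0), cmax_total = numeric(0),
                                cmax_free = numeric(0)),
                     class = c("dose_cmax_map", "data.frame")))
  stopifnot(all(doses >= 0), !is.unsorted(doses))
  cm <- vapply(doses, function(d0) {
    r <- simulate_pbk(d0, phys, part, kin, duration, ...)
    c(r$cmax_cpo_total, r$cmax_cpo_free)
  }, numeric(2))
  map <- data.frame(dose = doses, cmax_total = cm[1, ], cmax_free = cm[2, ])
  if (any(diff(map$cmax_free) < -1e-9 * max(map$cmax_free)))
    stop("free Cmax is not monotone in dose")
  structure(map, class = c("dose_cmax_map", "data.frame"))
}

#' Normalised sensitivity coefficients of the free blood CPO Cmax
#'
#' One-at-a-time perturbation: each parameter is multiplied by
#' `1 + perturbation`, the model is re-run (kinetic scaling is rebuilt, so
#' body-weight-covariant quantities respond consistently), and
#' `SC = (dCmax/Cmax) / (dP/P)` is reported.
#'
#' @param dose oral CPF dose (mg/kg bw)
#' @param mode kinetic mode passed to [liver_kinetics()]
#' @param perturbation fractional change in (0, 0.1]
#' @param parameters character vector of parameter names; any of the
#'   physiology fields (`bw`, `vlc`, `vbc`, `qcc`, `qlc`, `qrc`, `ka`, `fa`,
#'   `mpl`, `ke_tcpy`), partition fields (`fu_cpo_plasma`, `bp_cpo`,
#'   `bp_cpf`) or kinetic multipliers (`p1_vmax`, `p2_vmax`, `p3_vmax`,
#'   `p3_km`, `p4_vmax`, `p4_km`)
#' @param phys,part baseline parameter objects
#' @return data.frame `parameter`, `sc`, sorted by `abs(sc)` decreasing.
#' @export
sensitivity_analysis <- function(dose, mode = "supersome",
                                 perturbation = 0.05,
                                 parameters = c("bw", "vlc", "vbc", "qcc",
                                                "qlc", "qrc", "ka", "fa",
                                                "mpl", "fu_cpo_plasma",
                                                "bp_cpo", "bp_cpf",
                                                "p1_vmax", "p3_vmax",
                                                "p3_km", "p4_vmax", "p4_km"),
                                 phys = default_physiology(),
                                 part = default_partitioning()) {
  stopifnot(perturbation > 0, perturbation <= 0.1)
  run <- function(ph, pa, kmult) {
    kin <- liver_kinetics(mode, phys = ph)
    kin$p1$vmax <- kin$p1$vmax * kmult["p1_vmax"]
    kin$p2$vmax <- kin$p2$vmax * kmult["p2_vmax"]
    kin$p3$vmax <- kin$p3$vmax * kmult["p3_vmax"]
    kin$p3$km <- kin$p3$km * kmult["p3_km"]
    kin$p4$vmax <- kin$p4$vmax * kmult["p4_vmax"]
    kin$p4$km <- kin$p4$km * kmult["p4_km"]
    simulate_pbk(dose, ph, pa, kin)$cmax_cpo_free
  }
  km0 <- c(p1_vmax = 1, p2_vmax = 1, p3_vmax = 1, p3_km = 1, p4_vmax = 1,
           p4_km = 1)
  base <- run(phys, part, km0)
  sc <- vapply(parameters, function(nm) {
    ph <- phys; pa <- part; km <- km0
    if (nm %in% names(ph)) {
      ph[[nm]] <- ph[[nm]] * (1 + perturbation)
    } else if (nm %in% names(km)) {
      km[nm] <- 1 + perturbation
    } else if (nm %in% names(pa)) {
      pa[[nm]] <- pa[[nm]] * (1 + perturbation)
      if (nm %in% c("fu_cpo_plasma", "bp_cpo"))
        pa$fu_cpo_blood <- pa$fu_cpo_plasma / pa$bp_cpo
    } else stop("unknown parameter: ", nm)
    (run(ph, pa, km) - base) / base / perturbation
  }, numeric(1))
  out <- data.frame(parameter = parameters, sc = unname(sc))
  out[order(-abs(out$sc)), ]
}
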