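# Reference parameter sets: in vitro kinetics of CPF biotransformation,
# CYP phenotype abundances/frequencies, human physiology and partitioning.
# Units follow the conventions used throughout the package:
#   apparent Vmax  - pmol/min/pmol CYP (recombinant CYP), nmol/min/mg
#                    microsomal protein (HLM), nmol/min/ml plasma (plasma)
#   Km             - uM;  in vivo Vmax - umol/h;  CE - l/h

#' Molecular weights (g/mol) of chlorpyrifos and its metabolites
#'
#' @return Named numeric vector with elements `cpf`, `cpo`, `tcpy`.
#' @export
molecular_weights <- function() {
  c(cpf = 350.59, cpo = 334.52, tcpy = 198.43)
}

#' Apparent Michaelis-Menten kinetics of recombinant CYP preparations
#'
#' Apparent kinetic constants for CPF bioactivation to CPO (pathway 1) and
#' detoxification to TCPy (pathway 2) measured in incubations with single-CYP
#' recombinant (Supersome-type) preparations, together with the probe-substrate
#' data used to derive intersystem extrapolation factors (ISEF) and the mean
#' CYP abundances in pooled human liver microsomes.
#'
#' `isef` holds the reported two-decimal ISEFs, which are used by default for
#' scaling; `compute_isef()` recomputes them from the probe Vmax pairs (the
#' rounded probe Vmax of CYP2C19 does not reproduce its reported ISEF, which
#' is why the reported values are the default).
#'
#' @return data.frame, one row per CYP isoform (1A2, 2B6, 2C19, 3A4), columns:
#'   `cyp`, `abundance` (pmol CYP/mg microsomal protein), `vmax_hlm_probe`
#'   (nmol/min/mg), `vmax_ss_probe` (pmol/min/pmol CYP), `isef`,
#'   `km1`, `vmax1`, `km2`, `vmax2` (apparent pathway-1/2 kinetics, uM and
#'   pmol/min/pmol CYP).
#' @export
supersome_kinetics <- function() {
  data.frame(
    cyp            = c("1A2", "2B6", "2C19", "3A4"),
    abundance      = c(52.00, 15.80, 5.40, 137.00),
    vmax_hlm_probe = c(0.15, 0.31, 0.02, 17.29),
    vmax_ss_probe  = c(39.06, 40.77, 20.59, 1179),
    isef           = c(0.07, 0.48, 0.21, 0.11),
    km1            = c(0.61, 0.14, 1.89, 29.77),
    vmax1          = c(3.96, 7.76, 2.74, 17.78),
    km2            = c(1.25, 1.28, 1.37, 18.13),
    vmax2          = c(2.96, 5.49, 17.51, 23.86),
    stringsAsFactors = FALSE
  )
}

#' CYP phenotype abundances, coefficients of variation and frequencies
#'
#' Per-phenotype mean hepatic abundance (pmol CYP/mg microsomal protein), its
#' coefficient of variation and the phenotype frequency in the general
#' population, used by the Monte Carlo simulation of the recombinant-CYP-based
#' model. CYP2C19 poor metabolisers carry zero abundance.
#'
#' @return data.frame with columns `cyp`, `phenotype` (EM/PM/UM), `abundance`,
#'   `cv`, `frequency`.
#' @export
phenotype_table <- function() {
  data.frame(
    cyp       = c("1A2", "2B6", "2B6", "2C19", "2C19", "2C19", "3A4"),
    phenotype = c("EM", "EM", "PM", "EM", "PM", "UM", "EM"),
    abundance = c(52.0, 17.0, 6.0, 4.4, 0.0, 8.7, 137.0),
    cv        = c(0.67, 1.22, 2.00, 0.71, 0.00, 0.71, 0.41),
    frequency = c(1.000, 0.890, 0.110, 0.590, 0.092, 0.318, 1.000),
    stringsAsFactors = FALSE
  )
}

#' Pooled-HLM and plasma kinetic parameters with population CVs
#'
#' Apparent kinetics of the pooled-HLM description of CPF bioactivation
#' (biphasic: high- plus low-affinity phase) and detoxification, hepatic
#' PON1-mediated CPO hydrolysis (pathway 3) and plasma PON1-mediated CPO
#' hydrolysis (pathway 4, mean of a 25-individual plasma panel), with the
#' coefficients of variation used for Monte Carlo sampling.
#'
#' @return Nested list with elements `p1_high`, `p1_low`, `p2`, `p3`, `p4`;
#'   each holds `vmax`, `km`, `cv_vmax`, `cv_km` and a `units` tag for Vmax.
#' @export
hlm_kinetics <- function() {
  list(
    p1_high = list(vmax = 0.275, km = 0.270, cv_vmax = 0.59, cv_km = 0.61,
                   units = "nmol/min/mg"),
    p1_low  = list(vmax = 0.353, km = 29.80, cv_vmax = 0.59, cv_km = 0.61,
                   units = "nmol/min/mg"),
    p2      = list(vmax = 0.653, km = 12.00, cv_vmax = 0.53, cv_km = 0.89,
                   units = "nmol/min/mg"),
    p3      = list(vmax = 37.98, km = 627.9, cv_vmax = 0.57, cv_km = 0.39,
                   units = "nmol/min/mg"),
    p4      = list(vmax = 1844, km = 290, cv_vmax = 0.29, cv_km = 0.33,
                   units = "nmol/min/ml plasma")
  )
}

#' Human physiology parameters for the PBK model
#'
#' Adult (70 kg) reference physiology. Tissue volumes are fractions of body
#' weight; blood flows are fractions of cardiac output `qc = qcc * bw^0.74`.
#' The liver fraction `vlc = 0.0257` gives VL of about 1.8 kg at 70 kg body
#' weight; the blood fraction `vbc = 0.0753` is consistent with the whole-body
#' scaling of plasma PON1 activity. `fa` defaults to the mean of the two
#' reported human oral absorption fractions (0.224 and 0.7).
#'
#' @param bw body weight (kg)
#' @param fa oral fraction absorbed (dimensionless, <= 1)
#' @param ka first-order oral absorption rate constant (1/h)
#' @param mpl microsomal protein yield (mg/g liver)
#' @return Object of class `physiology_params` (a named list).
#' @export
default_physiology <- function(bw = 70, fa = mean(c(0.224, 0.7)), ka = 0.46,
                               mpl = 32) {
  p <- list(
    bw = bw,
    vlc = 0.0257, vbc = 0.0753, vfc = 0.214, vrc = 0.050, vsc = 0.540,
    qcc = 15,                       # L/h/kg^0.74
    qlc = 0.25, qfc = 0.05, qrc = 0.44, qsc = 0.26,
    ka = ka, fa = fa, mpl = mpl,
    ke_tcpy = 0.026                 # 1/h, urinary elimination of TCPy
  )
  stopifnot(p$fa <= 1, p$fa > 0, p$ka > 0, p$mpl > 0,
            sum(p$vlc, p$vbc, p$vfc, p$vrc, p$vsc) < 1,
            abs(p$qlc + p$qfc + p$qrc + p$qsc - 1) < 1e-9)
  class(p) <- "physiology_params"
  p
}

#' Derived physiology: volumes (L) and flows (L/h)
#'
#' @param phys `physiology_params`
#' @return Named list with `vl`, `vb`, `vf`, `vr`, `vs` (L, density 1 assumed)
#'   and `qc`, `ql`, `qf`, `qr`, `qs` (L/h).
#' @export
physiology_derived <- function(phys) {
  qc <- phys$qcc * phys$bw^0.74
  list(
    vl = phys$vlc * phys$bw, vb = phys$vbc * phys$bw,
    vf = phys$vfc * phys$bw, vr = phys$vrc * phys$bw,
    vs = phys$vsc * phys$bw,
    qc = qc, ql = phys$qlc * qc, qf = phys$qfc * qc,
    qr = phys$qrc * qc, qs = phys$qsc * qc
  )
}

# Tissue composition (fraction neutral lipid, fraction water) used for
# logP-based partition coefficient estimation.
.tissue_composition <- function() {
  list(
    blood  = c(lipid = 0.0037, water = 0.83),
    liver  = c(lipid = 0.042,  water = 0.735),
    fat    = c(lipid = 0.853,  water = 0.12),
    richly = c(lipid = 0.042,  water = 0.78),
    slowly = c(lipid = 0.019,  water = 0.76)
  )
}

#' Tissue:blood partition coefficient from logP
#'
#' Lipid/water composition ratio: `P = (fl_t*K + fw_t) / (fl_b*K + fw_b)` with
#' `K = 10^logP`. A deliberately simple estimate; partition coefficients enter
#' the model through [default_partitioning()] where they can be overridden.
#'
#' @param logp octanol-water log partition coefficient
#' @param tissue one of `"liver"`, `"fat"`, `"richly"`, `"slowly"`
#' @return dimensionless tissue:blood partition coefficient
#' @export
partition_from_logp <- function(logp, tissue) {
  comp <- .tissue_composition()
  stopifnot(tissue %in% setdiff(names(comp), "blood"))
  k <- 10^logp
  t <- comp[[tissue]]; b <- comp$blood
  (t["lipid"] * k + t["water"]) / (b["lipid"] * k + b["water"])
}

#' Partitioning and protein-binding parameters for CPF and CPO
#'
#' Tissue:blood partition coefficients are computed from logP (CPF 4.784,
#' CPO 3.89) unless supplied. The free fraction of CPO in blood is derived
#' from its plasma free fraction and blood:plasma ratio,
#' `fu_blood = fu_plasma / bp_cpo`.
#'
#' @param fu_cpo_plasma unbound fraction of CPO in plasma
#' @param bp_cpo CPO blood:plasma concentration ratio
#' @param bp_cpf CPF blood:plasma concentration ratio
#' @param logp_cpf,logp_cpo octanol-water logP values
#' @param pc optional named list overriding any of `pl_cpf`, `pf_cpf`,
#'   `pr_cpf`, `ps_cpf`, `pl_cpo`, `px_cpo`
#' @return Object of class `partition_params`.
#' @export
default_partitioning <- function(fu_cpo_plasma = 0.15, bp_cpo = 2.7,
                                 bp_cpf = 1.3, logp_cpf = 4.784,
                                 logp_cpo = 3.89, pc = list()) {
  stopifnot(fu_cpo_plasma > 0, fu_cpo_plasma <= 1, bp_cpo > 0, bp_cpf > 0)
  p <- list(
    fu_cpo_plasma = fu_cpo_plasma,
    bp_cpo = bp_cpo,
    bp_cpf = bp_cpf,
    fu_cpo_blood = fu_cpo_plasma / bp_cpo,
    pl_cpf = unname(partition_from_logp(logp_cpf, "liver")),
    pf_cpf = unname(partition_from_logp(logp_cpf, "fat")),
    pr_cpf = unname(partition_from_logp(logp_cpf, "richly")),
    ps_cpf = unname(partition_from_logp(logp_cpf, "slowly")),
    pl_cpo = unname(partition_from_logp(logp_cpo, "liver")),
    px_cpo = unname(partition_from_logp(logp_cpo, "richly"))
  )
  p[names(pc)] <- pc
  class(p) <- "partition_params"
  p
}

#' Other influential parameter distributions for Monte Carlo sampling
#'
#' Means and CVs of the non-kinetic parameters sampled in the
#' "all influential" Monte Carlo scope: body weight (which drives the
#' BW-covariant volumes and flows), ka, fa (upper bound capped at 1), MPL and
#' the CPO plasma free fraction (with the blood:plasma ratio tied to the fu
#' draw).
#'
#' @return data.frame with columns `parameter`, `mean`, `cv`, `cap`.
#' @export
influential_parameter_table <- function() {
  data.frame(
    parameter = c("bw", "ka", "fa", "mpl", "fu_cpo_plasma"),
    mean      = c(70, 0.46, mean(c(0.224, 0.7)), 32, 0.15),
    cv        = c(0.30, 0.30, 0.73, 0.46, 0.30),
    cap       = c(NA, NA, 1, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Blood:plasma ratio of CPO as a function of its plasma free fraction
#'
#' The variability of the CPO blood:plasma ratio is treated as fully
#' correlated with the plasma free fraction through a red-blood-cell
#' partitioning identity, `BP = (1 - Hct) + Hct * Krbc * fu`, with the
#' red-cell affinity constant fixed so that `BP(0.15) = 2.7` at a haematocrit
#' of 0.45. Higher free fraction implies more red-cell uptake and a higher
#' blood:plasma ratio.
#'
#' @param fu_plasma plasma free fraction draw(s)
#' @param hct haematocrit
#' @param bp_ref,fu_ref reference pair anchoring the affinity constant
#' @return blood:plasma ratio(s)
#' @export
bp_cpo_from_fu <- function(fu_plasma, hct = 0.45, bp_ref = 2.7, fu_ref = 0.15) {
  krbc <- (bp_ref - (1 - hct)) / (hct * fu_ref)
  (1 - hct) + hct * krbc * fu_plasma
}
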