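# Michaelis-Menten fitting, ISEF computation and in-vitro to in-vivo scaling
# of apparent kinetic constants.

#' Michaelis-Menten parameter container
#'
#' @param vmax_app apparent maximum velocity (units depend on enzyme source)
#' @param km_app apparent Michaelis constant (uM)
#' @param units character tag describing the Vmax units
#' @param se optional named numeric vector of standard errors (`vmax`, `km`)
#' @param rss optional residual sum of squares of the fit
#' @return Object of class `mm_params` with fields `vmax_app`, `km_app`,
#'   `ce_app` (= vmax/km), `units`, `se`, `rss`.
#' @export
mm_params <- function(vmax_app, km_app, units = "unspecified", se = NULL,
                      rss = NULL) {
  if (!is.finite(vmax_app) || vmax_app <= 0)
    stop("vmax_app must be a positive finite number")
  if (!is.finite(km_app) || km_app <= 0)
    stop("km_app must be a positive finite number")
  structure(list(vmax_app = vmax_app, km_app = km_app,
                 ce_app = vmax_app / km_app, units = units, se = se,
                 rss = rss),
            class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("Michaelis-Menten: Vmax(app) = %.4g [%s], Km(app) = %.4g uM, CE = %.4g\n",
              x$vmax_app, x$units, x$km_app, x$ce_app))
  invisible(x)
}

#' Michaelis-Menten velocity
#'
#' @param s substrate concentration(s) (uM)
#' @param vmax maximum velocity
#' @param km Michaelis constant (uM)
#' @return velocity in the units of `vmax`
#' @export
mm_rate <- function(s, vmax, km) vmax * s / (km + s)

#' Fit apparent Michaelis-Menten kinetics to incubation data
#'
#' Nonlinear least-squares fit of `v = Vmax*S/(Km+S)`. Relative (proportional)
#' weighting is the default because in vitro velocities commonly span orders
#' of magnitude across the concentration design; absolute weighting is
#' available. Start values come from a Hanes-Woolf linearisation with a
#' direct-search fallback.
#'
#' @param concentrations substrate concentrations (uM), at least 4 distinct
#' @param velocities observed velocities (>= 0), same length
#' @param units character tag for the Vmax units
#' @param weighting `"relative"` or `"absolute"`
#' @return `mm_params` with standard errors and residual sum of squares.
#' @export
fit_michaelis_menten <- function(concentrations, velocities,
                                 units = "unspecified",
                                 weighting = c("relative", "absolute")) {
  weighting <- match.arg(weighting)
  s <- as.numeric(concentrations); v <- as.numeric(velocities)
  stopifnot(length(s) == length(v))
  if (length(unique(s)) < 4)
    stop("need at least 4 distinct concentrations")
  if (any(s <= 0)) stop("concentrations must be positive")
  if (any(v < 0)) stop("velocities must be nonnegative")
  if (all(v <= 0) || max(v) == 0)
    stop("Michaelis-Menten fit failed: all velocities are zero (no saturation information)")

  # Hanes-Woolf start: s/v = km/vmax + s/vmax (positive velocities only)
  pos <- v > 0
  hw <- try(lm(I(s[pos] / v[pos]) ~ s[pos]), silent = TRUE)
  start <- NULL
  if (!inherits(hw, "try-error")) {
    slope <- coef(hw)[2]; icpt <- coef(hw)[1]
    if (is.finite(slope) && slope > 0 && is.finite(icpt) && icpt > 0)
      start <- list(vmax = unname(1 / slope), km = unname(icpt / slope))
  }
  if (is.null(start))
    start <- list(vmax = max(v) * 1.2, km = stats::median(s))

  w <- if (weighting == "relative") 1 / pmax(v, max(v) * 1e-3)^2 else rep(1, length(v))
  fit <- try(minpack.lm::nlsLM(
    v ~ vmax * s / (km + s),
    start = start, weights = w,
    lower = c(vmax = 0, km = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Michaelis-Menten fit failed to converge")
  est <- coef(fit)
  if (any(!is.finite(est)) || any(est <= 0))
    stop("Michaelis-Menten fit failed: non-positive parameter estimate")
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  mm_params(unname(est["vmax"]), unname(est["km"]), units = units,
            se = c(vmax = unname(se[1]), km = unname(se[2])),
            rss = sum(residuals(fit)^2))
}

#' Intersystem extrapolation factor from probe-substrate Vmax values
#'
#' `ISEF = Vmax_probe(pooled HLM) * 1000 / (Vmax_probe(recombinant) * abundance)`,
#' where the HLM probe Vmax is in nmol/min/mg microsomal protein, the
#' recombinant Vmax in pmol/min/pmol CYP, and the abundance in pmol CYP/mg
#' microsomal protein (the factor 1000 converts nmol to pmol).
#'
#' @param vmax_pooled_hlm probe Vmax in pooled HLM (nmol/min/mg)
#' @param vmax_supersome probe Vmax in the recombinant preparation
#'   (pmol/min/pmol CYP)
#' @param abundance mean CYP abundance in HLM (pmol/mg)
#' @return dimensionless ISEF
#' @export
compute_isef <- function(vmax_pooled_hlm, vmax_supersome, abundance) {
  if (!is.finite(abundance) || abundance <= 0)
    stop("ISEF undefined: CYP abundance must be positive")
  if (!is.finite(vmax_supersome) || vmax_supersome <= 0)
    stop("ISEF undefined: recombinant probe Vmax must be positive")
  if (!is.finite(vmax_pooled_hlm) || vmax_pooled_hlm <= 0)
    stop("ISEF undefined: pooled-HLM probe Vmax must be positive")
  vmax_pooled_hlm * 1000 / (vmax_supersome * abundance)
}

#' Scale recombinant-CYP apparent Vmax to whole-body Vmax
#'
#' `Vmax = Vmax_app * abundance * ISEF * 60 * MPL * 1000 * VL / 1e6`,
#' converting pmol/min/pmol CYP to umol/h for the whole liver.
#'
#' @param vmax_app apparent Vmax (pmol/min/pmol CYP)
#' @param abundance CYP abundance (pmol/mg microsomal protein); may be zero
#'   (null phenotype), giving zero
#' @param isef intersystem extrapolation factor
#' @param mpl microsomal protein yield (mg/g liver)
#' @param vl liver weight (kg)
#' @return in vivo Vmax (umol/h)
#' @export
scale_supersome_vmax <- function(vmax_app, abundance, isef, mpl, vl) {
  stopifnot(vmax_app >= 0, abundance >= 0, isef >= 0, mpl > 0, vl > 0)
  vmax_app * abundance * isef * 60 * mpl * 1000 * vl / 1e6
}

#' Scale HLM apparent Vmax to whole-body Vmax
#'
#' `Vmax = Vmax_app * 60 * MPL * 1000 * VL / 1000` (nmol/min/mg microsomal
#' protein to umol/h for the whole liver).
#'
#' @param vmax_app apparent Vmax (nmol/min/mg microsomal protein)
#' @param mpl microsomal protein yield (mg/g liver)
#' @param vl liver weight (kg)
#' @return in vivo Vmax (umol/h)
#' @export
scale_hlm_vmax <- function(vmax_app, mpl, vl) {
  stopifnot(vmax_app >= 0, mpl > 0, vl > 0)
  vmax_app * 60 * mpl * 1000 * vl / 1000
}

#' Scale plasma apparent Vmax to whole-body Vmax
#'
#' `Vmax = Vmax_app * 60 * 1000 * VB * 0.55 / 1000` (nmol/min/ml plasma to
#' umol/h), where 0.55 is the plasma fraction of blood volume, so that plasma
#' PON1 activity measured per ml plasma applies to the plasma of the whole
#' blood compartment.
#'
#' @param vmax_app apparent Vmax (nmol/min/ml plasma)
#' @param vb blood volume (L); zero gives zero
#' @param plasma_fraction plasma fraction of blood volume
#' @return in vivo Vmax (umol/h)
#' @export
scale_plasma_vmax <- function(vmax_app, vb, plasma_fraction = 0.55) {
  stopifnot(vmax_app >= 0, vb >= 0, plasma_fraction > 0, plasma_fraction <= 1)
  vmax_app * 60 * 1000 * vb * plasma_fraction / 1000
}

#' Scaled per-isoform kinetics for one pathway
#'
#' Applies [scale_supersome_vmax()] to every isoform row of a
#' [supersome_kinetics()]-style table and returns the whole-body Vmax
#' (umol/h), Km (uM) and catalytic efficiency (l/h) per isoform.
#'
#' @param isoforms data.frame as from [supersome_kinetics()]
#' @param pathway 1 (bioactivation to CPO) or 2 (detoxification to TCPy)
#' @param mpl microsomal protein yield (mg/g liver)
#' @param vl liver weight (kg)
#' @param isef optional ISEF vector overriding the table column
#' @return data.frame with columns `cyp`, `vmax_invivo`, `km`, `ce_invivo`.
#' @export
scaled_pathway <- function(isoforms, pathway, mpl, vl, isef = NULL) {
  stopifnot(pathway %in% c(1, 2), nrow(isoforms) >= 1)
  if (is.null(isef)) isef <- isoforms$isef
  km <- if (pathway == 1) isoforms$km1 else isoforms$km2
  va <- if (pathway == 1) isoforms$vmax1 else isoforms$vmax2
  vmax <- mapply(scale_supersome_vmax, va, isoforms$abundance, isef,
                 MoreArgs = list(mpl = mpl, vl = vl))
  data.frame(cyp = isoforms$cyp, vmax_invivo = vmax, km = km,
             ce_invivo = vmax / km, stringsAsFactors = FALSE)
}

#' Summed scaled catalytic efficiency over CYP isoforms
#'
#' @inheritParams scaled_pathway
#' @return total catalytic efficiency (l/h), the sum of scaled Vmax / Km.
#' @export
summed_scaled_ce <- function(isoforms, pathway, mpl, vl, isef = NULL) {
  sum(scaled_pathway(isoforms, pathway, mpl, vl, isef)$ce_invivo)
}

#' Eadie-Hofstee diagnostic for biphasic kinetics
#'
#' Transforms a velocity curve to Eadie-Hofstee coordinates (v versus v/S).
#' A single Michaelis-Menten enzyme gives a straight line; a mixture of
#' enzymes with well-separated Km values gives a bent curve. The curve is
#' flagged biphasic when (i) the single line shows a material lack of fit
#' (SSE exceeding `lof_threshold` of the total sum of squares, so that a
#' near-perfect line is never split on numerical noise alone) and (ii) the
#' best two-segment linear fit reduces the single-line residual sum of
#' squares by at least `sse_factor`.
#'
#' @param s concentration grid (uM), strictly positive, increasing
#' @param v velocities on the grid
#' @param sse_factor required fractional SSE reduction (default 0.5)
#' @param lof_threshold single-line lack-of-fit fraction of total sum of
#'   squares below which the curve counts as one line (default 0.15)
#' @return list with `table` (data.frame of `s`, `v`, `v_over_s`),
#'   `sse_one`, `sse_two`, `lack_of_fit` (sse_one / total SS), `biphasic`
#'   (logical).
#' @export
eadie_hofstee_diagnostic <- function(s, v, sse_factor = 0.5,
                                     lof_threshold = 0.15) {
  stopifnot(length(s) == length(v), all(s > 0), all(diff(s) > 0),
            length(s) >= 6)
  x <- v / s
  ord <- order(x)
  xo <- x[ord]; vo <- v[ord]
  sse <- function(xx, vv) {
    if (length(unique(xx)) < 2) return(sum((vv - mean(vv))^2))
    sum(residuals(lm(vv ~ xx))^2)
  }
  sse_one <- sse(xo, vo)
  n <- length(xo)
  sse_two <- Inf
  for (k in 3:(n - 3)) {
    s2 <- sse(xo[1:k], vo[1:k]) + sse(xo[(k + 1):n], vo[(k + 1):n])
    if (s2 < sse_two) sse_two <- s2
  }
  tss <- sum((vo - mean(vo))^2)
  lof <- if (tss > 0) sse_one / tss else 0
  list(table = data.frame(s = s, v = v, v_over_s = x),
       sse_one = sse_one, sse_two = sse_two, lack_of_fit = lof,
       biphasic = lof > lof_threshold &&
         (sse_two <= (1 - sse_factor) * sse_one))
}

#' Table of apparent, ISEF and scaled kinetics for export
#'
#' Assembles the per-isoform apparent kinetics, ISEFs and whole-body scaled
#' values for both pathways into one structure, and optionally writes it as
#' JSON.
#'
#' @param isoforms data.frame as from [supersome_kinetics()]
#' @param mpl,vl scaling constants (mg/g liver; kg liver)
#' @param file optional path; when given, the structure is written as JSON
#' @return Invisibly, a list with `apparent`, `pathway1`, `pathway2`.
#' @export
export_kinetics_table <- function(isoforms = supersome_kinetics(), mpl = 32,
                                  vl = 1.8, file = NULL) {
  out <- list(
    apparent = isoforms,
    pathway1 = scaled_pathway(isoforms, 1, mpl, vl),
    pathway2 = scaled_pathway(isoforms, 2, mpl, vl)
  )
  if (!is.null(file))
    jsonlite::write_json(out, file, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  invisible(out)
}
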