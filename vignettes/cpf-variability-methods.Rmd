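---
title: "Methods: chlorpyrifos toxicokinetic variability, from incubation kinetics to BMDL10"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chlorpyrifos toxicokinetic variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpfvar)
```

`cpfvar` implements an end-to-end quantitative in-vitro-to-in-vivo
extrapolation (QIVIVE) workflow for the organophosphate insecticide
chlorpyrifos (CPF). Its bioactive metabolite chlorpyrifos-oxon (CPO)
irreversibly inhibits acetylcholinesterase (AChE); red-blood-cell AChE
inhibition is the critical effect used for points of departure in risk
assessment. The package covers four stages:

1. **Kinetic scaling** — apparent Michaelis-Menten constants measured in
   vitro (single-CYP recombinant preparations, pooled human liver
   microsomes, or individual plasma) are scaled to whole-body maximum
   velocities.
2. **PBK simulation** — a compartmental, flow-limited physiologically based
   kinetic model predicts blood CPF/CPO and urinary TCPy after a single
   oral dose.
3. **Population Monte Carlo** — inter-individual variability is propagated
   through the model from truncated lognormal parameter distributions and a
   CYP phenotype mixture, yielding the chemical-specific adjustment factor
   HKAF (a high percentile of the free blood CPO Cmax over its geometric
   mean).
4. **Reverse dosimetry and BMD** — an in vitro CPO concentration-response
   curve for AChE inhibition is translated into in vivo dose-response
   curves (average, sensitive and insensitive percentiles) and a BMDL10 is
   derived.

## Metabolic pathways and their scaling

Four reactions are modelled: (1) hepatic CYP-mediated bioactivation
CPF → CPO, (2) hepatic CYP-mediated detoxification CPF → TCPy, (3) hepatic
PON1-mediated hydrolysis CPO → TCPy, and (4) plasma PON1-mediated
hydrolysis CPO → TCPy.

Two alternative descriptions of the hepatic CYP reactions are supported.

**Recombinant-CYP ("Supersome") description.** Per-isoform apparent
kinetics (CYP1A2, 2B6, 2C19, 3A4; `supersome_kinetics()`) are summed as

$$v = \sum_i \frac{V_{\max,i}\,[S]}{K_{m,i}+[S]},\qquad
V_{\max,i} = V_{\max,i}^{app}\cdot A_i\cdot \mathrm{ISEF}_i\cdot
60\cdot \mathrm{MPL}\cdot 1000\cdot V_L/10^6,$$

where $A_i$ is the CYP abundance (pmol/mg microsomal protein), MPL the
microsomal protein yield (32 mg/g liver) and $V_L$ the liver weight (kg).
The intersystem extrapolation factor normalises the high specific activity
of the recombinant system to microsomal activity via a probe substrate:
$\mathrm{ISEF}_i = V^{probe}_{\max,HLM} \times 1000 / (V^{probe}_{\max,rCYP}
\times A_i)$. The two-decimal reported ISEFs (0.07 / 0.48 / 0.21 / 0.11)
are the package default because the CYP2C19 value cannot be reproduced from
the rounded probe velocities (they give 0.18); `compute_isef()` recomputes
ISEFs from probe data when exact inputs are available.

**Pooled-HLM description.** Pathway 1 is biphasic — a high-affinity phase
($V_{\max}$ 0.275 nmol/min/mg, $K_m$ 0.27 µM) plus a low-affinity phase
(0.353 nmol/min/mg, 29.8 µM) — because a pooled microsomal measurement over
a high concentration range only captures the low-affinity (CYP3A4-like)
component, while the low-Km CYPs dominate at sub-micromolar
concentrations. A non-biphasic variant (low-affinity phase only) is
retained purely as a negative control: it under-predicts CPO formation at
realistic doses (summed catalytic efficiency 41 l/h versus ~3560 l/h
biphasic and ~1570 l/h for the scaled recombinant sum).
`eadie_hofstee_diagnostic()` flags biphasic behaviour when a two-segment
line fit reduces the one-line residual sum of squares by ≥50% *and* the
one-line lack of fit exceeds 15% of the total sum of squares; the second
guard stops a numerically perfect single line from being split on noise,
and both thresholds are adjustable arguments.

Whole-body scaling constants: liver weight $V_L = 0.0257\,BW$ (about 1.8 kg
at 70 kg). Blood volume $V_B = 0.0753\,BW$; this fraction was back-derived
so that the mean plasma PON1 activity of 1844 nmol/min/ml scales to the
whole-body value of ~3.2×10^5 µmol/h via
$V_{\max} = V^{app}_{\max}\cdot 60\cdot 1000\cdot V_B\cdot 0.55/1000$
(plasma is 55% of blood volume). Both fractions live in
`default_physiology()` and can be overridden.

## PBK model structure

The compartment structure is a reconstruction: the model it extends is not
reprinted anywhere accessible, so the package uses the minimal standard CPF
architecture that supports the four pathways and the reported outputs. CPF:
gut lumen (first-order absorption `ka` of the absorbable fraction `fa`,
delivered to the liver; the unabsorbed remainder never enters), liver,
blood, fat, richly and slowly perfused tissue, all flow-limited. CPO:
liver, blood and a lumped rapidly equilibrating rest compartment. TCPy: one
body pool with first-order urinary elimination (0.026 /h, half-life ~27 h,
chosen once so cumulative urinary excretion approaches completeness by
~120 h). Metabolism acts on the liver venous concentration (pathways 1-3)
and on total blood CPO (pathway 4; a switch `p4_on_free` restricts it to
the free concentration, since the original convention is not documented).

Tissue:blood partition coefficients are not reported either; they are
estimated from logP (CPF 4.784, CPO 3.89) with a neutral-lipid/water
composition ratio (`partition_from_logp()`) and stored in
`default_partitioning()` for overriding. The HKAF is a ratio of percentiles
to the geometric mean of the same quantity, so it is insensitive to these
absolute partition values to first order.

The right-hand side is compiled C (deSolve), because the Monte Carlo stage
solves the system tens of thousands of times; an identical pure-R
implementation is kept and the test suite verifies both give the same
trajectories. Default tolerances are `rtol = 1e-8`, `atol = 1e-10`
(`1e-7`/`1e-9` inside the Monte Carlo loop); Cmax is refined by
re-integrating a dense 61-point grid across the bracketing interval of the
coarse-grid maximum. Mass balance (absorbed dose = sum of all molar pools)
holds to well below 0.1% at every output time and is recomputed on every
simulation.

At 0.47 mg/kg bw, hepatic extraction of CPF is largely flow-limited (summed
intrinsic clearance ≫ liver blood flow), so the free CPO Cmax is most
sensitive to absorption (`fa`, `ka`), body-weight-covariant physiology, the
CPO free fraction/blood:plasma ratio, and the PON1 detoxification kinetics
— the pattern `sensitivity_analysis()` reports.

## Population Monte Carlo and HKAF

Each sampled parameter follows a lognormal distribution specified by its
arithmetic mean and CV, transformed to log space as
$\sigma_w^2 = \ln(1+CV^2)$, $\mu_w = \ln(\mu/\sqrt{1+CV^2})$, sampled as
$\exp(\mathcal N(\mu_w,\sigma_w))$ and truncated at $\mu_w \pm 3\sigma_w$.
A run whose draw falls outside any bound is **discarded without
replacement**: accepted totals below the nominal count are part of the
reported output (with 13 sampled parameters and the `fa ≤ 1` cap treated as
an extra upper truncation bound, about 9% of runs are rejected, matching
the published accounting). Note that the ±3σ truncation itself shrinks the
realised CV a few percent below its nominal value; tests compare sampled
moments against the exact truncated-lognormal moments.

In the recombinant-CYP mode, variability of pathways 1-2 enters through the
CYP abundances only (one draw per CYP feeds both pathways); CYP2B6 and
CYP2C19 have multiple phenotypes (EM/PM/UM, `phenotype_table()`), giving
six phenotype combinations whose results are pooled with the product of
phenotype frequencies as weights (each accepted draw carries weight
`frequency / n_accepted` of its combination). The CYP2C19 poor-metaboliser
abundance is exactly zero and is not sampled. In the HLM mode the pathway
1-2 Vmax/Km values are sampled directly with their population CVs. Pathways
3 and 4 sample Vmax and Km independently in both modes; no correlation is
imposed between pathways (a conservative choice that maximises the spread).

The `all_influential` scope additionally samples body weight (CV 0.3; the
volumes and flows are recomputed from each BW draw rather than sampled
separately, as they are BW-covariant), `ka` (0.3), `fa` (0.73, capped at
1), MPL (0.46) and the CPO plasma free fraction (0.3). The CPO blood:plasma
ratio is a deterministic function of the free-fraction draw through a
red-cell partitioning identity $BP = (1-Hct) + Hct\,K_{rbc}\,fu$ with
haematocrit 0.45 and $K_{rbc}$ anchored so that $BP(0.15)=2.7$ — this
encodes the stated full correlation between the two parameters while
keeping the marginal mean at 2.7.

`run_population()` returns the weighted free-Cmax sample; HKAF is the
weighted 95th or 99th percentile (inverse weighted empirical CDF with
linear interpolation, switchable to nearest-rank) divided by the weighted
geometric mean. Per-combination RNG substreams (`seed*100 + combo`) make
runs reproducible and independent of execution order. The package default
of 2,000 draws per combination (12,000 runs per scope) keeps a full
population simulation around 20-30 s on one CPU while leaving the Monte
Carlo error of the 99th percentile at a few percent.

## Reverse dosimetry and benchmark dose

The in vitro assay reads 412 nm absorbance changes over 10 min; remaining
activity is anchored between the solvent control (100%) and a fully
inhibited positive control (0%). The concentration-response is a
four-parameter logistic on log concentration; the generator truth for the
synthetic plates has IC50 1.89 nM and Hill slope 1.

The in vitro free concentration (free fraction assumed 1; only trace
albumin is present in the assay) is equated with the in vivo free blood
Cmax: $C_{blood} = C_{vitro}\,fu_{vitro}/(fu_{plasma}/BP)$, with
$fu_{plasma} = 0.15$ and $BP = 2.7$ giving a blood free fraction of 0.0556.
`reverse_dose()` inverts the monotone dose → free-Cmax map by log-log
interpolation; the map's default grid is log-spaced with ≥25 points
covering the in-vitro-equivalent range. Reverse dosimetry moves only the
dose axis — response values are preserved exactly. The sensitive (P99) and
insensitive (P1) curves divide the dose axis by P99/GM (the HKAF) and
P1/GM respectively; dose-axis division is the standard way a kinetic
adjustment factor is applied, and the alternative (multiplying responses)
is not used.

BMD analysis fits two continuous families to the average-population
inhibition curve with background fixed at 0: Hill
($v\,d^n/(k^n+d^n)$) and exponential ($v\,(1-e^{-(d/b)^g})$). The BMR is a
10-percentage-point change in inhibition (the 10%-of-scale convention used
for AChE data). BMDL10 is the smallest benchmark dose within the one-sided
95% profile-likelihood region (deviance $n\log(RSS(B)/RSS_{min})$ against
$\chi^2_{0.90,1}$), with the scale parameter eliminated through the
constraint $f(B)=\mathrm{BMR}$; profiling is deterministic, unlike a
bootstrap. The model with the lowest AIC (normal likelihood, profiled
variance) is reported. This is a deliberately simplified continuous BMD
routine — it follows the model families and BMR convention of the
regulatory software but does not reproduce its exact numerics.

## Synthetic data: what it emulates and what it does not

`generate_incubation()`, `generate_plasma_panel()` and
`generate_ache_plate()` produce every input the pipeline consumes, each a
bit-exact function of its seed. Observation noise is multiplicative
lognormal (velocities and absorbances are positive and span decades) with a
default observation CV of 5% and 2 replicates per concentration, mirroring
duplicate-experiment designs. The plasma panel draws 25 individual
(Vmax, Km) pairs from the truncated lognormal population truths (means
1844 nmol/min/ml and 290 µM, CVs 0.29/0.33) independently — the same
independence assumption the Monte Carlo uses; individuals outside the
truncation bounds are redrawn so a panel always has its nominal size. The
generators do not emulate chromatographic raw signals, plate-reader time
series, detection limits, or any systematic (non-multiplicative) error, so
passing round-trip tests demonstrates estimator correctness under the
assumed noise model, not robustness to real-world assay artefacts.

## Design choices and limitations

* The compartmental structure and partition coefficients are reconstructed,
  not transcribed; absolute concentration predictions should be treated as
  approximate, while ratios (HKAF, fold comparisons between kinetic modes)
  are structurally robust. Comparisons against published in vivo
  concentration profiles are qualitative only.
* The recombinant-CYP and biphasic-HLM modes agree within ~1.15-fold on
  total CPO Cmax at sub-µM doses in this implementation, with the gap
  growing toward ~2-fold at strongly saturating doses.
* Default Monte Carlo problem sizes (2,000 draws per combination) are the
  package's standing choice for a single-CPU workflow; all statistics are
  reported with accepted-run counts so users can scale up.
* Adult reference physiology only; no sub-populations (pregnancy,
  children), no repeated dosing, no inhalation/dermal routes, and no other
  organophosphates.

```{r, eval = FALSE}
# A complete run of the primary workflow:
report <- run_pipeline("supersome", "all_influential",
                       n_per_combo = 2000, seed = 1)
print(report)
```
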