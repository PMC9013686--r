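# cpfvar

Inter-individual variability in chlorpyrifos toxicokinetics: in vitro
kinetics → PBK model → Monte Carlo population simulation → chemical-specific
adjustment factors → reverse dosimetry → benchmark dose.

Chlorpyrifos (CPF) is bioactivated by hepatic CYPs to chlorpyrifos-oxon
(CPO), which inhibits acetylcholinesterase (AChE); CPF and CPO are
detoxified to TCPy by CYPs and by paraoxonase-1 (PON1) in liver and plasma.
How strongly an individual responds to a given oral CPF dose depends on the
balance of these four reactions, which vary widely across people. `cpfvar`
is aimed at toxicokinetic modellers and risk assessors who want to:

* scale apparent Michaelis–Menten constants from recombinant single-CYP
  preparations (via intersystem extrapolation factors, ISEF), pooled human
  liver microsomes (including biphasic high/low-affinity kinetics) or
  individual plasma to whole-body values,
  `Vmax_i = Vmax_i(app) · abundance_i · ISEF_i · 60 · MPL · 1000 · VL / 10⁶`;
* predict blood CPF/CPO and urinary TCPy after a single oral dose with a
  flow-limited compartmental PBK model (compiled ODE core);
* propagate inter-individual variability — truncated lognormal parameter
  distributions (`σ_w² = ln(1+CV²)`, ±3σ rejection) mixed over CYP
  phenotype combinations — to the distribution of the free blood CPO Cmax,
  and compute the kinetic adjustment factor `HKAF = P95/GM` or `P99/GM`;
* translate an in vitro CPO–AChE inhibition curve (4-parameter logistic)
  into in vivo dose–response curves via free-concentration equivalence
  (`C_blood = C_vitro · fu_vitro / (fu_plasma/BP)`) and derive a BMDL₁₀ by
  profile likelihood from Hill/exponential fits.

A synthetic-data module generates every input the pipeline consumes
(incubation velocity datasets, a 25-individual plasma panel, 96-well AChE
plates), so the full workflow runs and is tested without any external data.

## Worked example

```r
library(cpfvar)

# Intersystem extrapolation factors from probe-substrate Vmax pairs
compute_isef(0.15, 39.06, 52)     # CYP1A2 -> 0.0739
compute_isef(0.31, 40.77, 15.8)   # CYP2B6 -> 0.481

# Whole-liver summed catalytic efficiency of the bioactivation pathway
vl <- physiology_derived(default_physiology())$vl   # 1.80 kg liver
summed_scaled_ce(supersome_kinetics(), 1, 32, vl)   # 1570 l/h

# One PBK simulation at the point-of-departure dose
simulate_pbk(0.47)
#> PBK simulation: Cmax CPO total 0.003056 uM (free 0.0001698 uM), Cmax CPF 0.003726 uM
#>   mass-balance residual 1.80e-15, urinary TCPy fraction 0.688

# Population variability, kinetic parameters only
run_population("supersome", "kinetic_only", n_per_combo = 2000, seed = 1)
#> Population simulation (supersome, kinetic_only) at 0.47 mg/kg bw
#>   accepted 11763 of 12000 runs (0 solver failures)
#>   GM 0.0001492 uM; P1 3.291e-05; P95 0.0003645; P99 0.0004908
#>   HKAF(95) = 2.44; HKAF(99) = 3.29; P1/GM = 0.22

# The full pipeline: in vitro fit, PBK map, Monte Carlo, reverse dosimetry, BMD
run_pipeline("supersome", "all_influential", n_per_combo = 2000, seed = 1)
#> Pipeline (supersome, all_influential): IC50 1.89 nM; HKAF95 3.90; HKAF99 6.10; BMDL10 0.496 mg/kg bw
```

Reading the numbers: an average 70 kg adult taking 0.47 mg/kg CPF orally
reaches a free blood CPO peak of ~1.7·10⁻⁴ µM. Sampling only the metabolic
variability, the 99th-percentile individual reaches ~3.3× the population
geometric mean; adding variability in absorption, physiology and plasma
binding raises that to ~6×. The reverse-dosimetry BMDL₁₀ of ~0.5 mg/kg bw
for the average population is the model's point of departure for a 10%
AChE inhibition.

## Documentation

The methods vignette (`vignettes/cpf-variability-methods.Rmd`) describes
the model equations and assumptions, the distributional choices of the
Monte Carlo, the numerical settings (solver tolerances, Cmax refinement,
profile-likelihood BMDL), what the synthetic-data generators do and do not
emulate, and the package's reconstruction choices and limitations.
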