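Package: cpfvar
Title: Chlorpyrifos Toxicokinetics, Population Variability and Reverse Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based kinetic (PBK) modelling of chlorpyrifos (CPF)
    bioactivation to chlorpyrifos-oxon (CPO) and detoxification to TCPy, with
    in vitro to in vivo scaling of Michaelis-Menten kinetics from recombinant
    CYP preparations (via intersystem extrapolation factors) or pooled human
    liver microsomes (biphasic kinetics). Monte Carlo simulation of
    inter-individual variability with truncated lognormal distributions and
    CYP phenotype mixtures yields chemical-specific adjustment factors
    (HKAF), and PBK-based reverse dosimetry translates in vitro
    acetylcholinesterase inhibition into in vivo dose-response curves with
    benchmark-dose (BMDL10) estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
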