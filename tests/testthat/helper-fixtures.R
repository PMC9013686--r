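# Shared fixtures: reference parameter objects and a hand-built biphasic
# kinetic description used across test files.

ref_phys <- default_physiology()
ref_part <- default_partitioning()

# Biphasic pathway-1 description with whole-liver Vmax values scaled at
# MPL 32 mg/g and VL 1.8 kg (0.275 and 0.353 nmol/min/mg apparent).
biphasic_kin_fixture <- function() {
  structure(list(
    mode = "hlm_biphasic",
    p1 = data.frame(vmax = c(950.4, 1219.9), km = c(0.270, 29.8)),
    p2 = data.frame(vmax = scale_hlm_vmax(0.653, 32, 1.8), km = 12),
    p3 = list(vmax = scale_hlm_vmax(37.98, 32, 1.8), km = 627.9),
    p4 = list(vmax = scale_plasma_vmax(1844, 5.271), km = 290)
  ), class = "liver_kinetics")
}

# Single-MM kinetic description (every pathway one term), used for the
# mode-reduction and closed-form checks.
single_mm_kin <- function(vmax1 = 100, km1 = 5) {
  structure(list(
    mode = "hlm_nonbiphasic",
    p1 = data.frame(vmax = vmax1, km = km1),
    p2 = data.frame(vmax = 50, km = 10),
    p3 = list(vmax = 1000, km = 600),
    p4 = list(vmax = 5000, km = 300)
  ), class = "liver_kinetics")
}

# Dose-response curve generated exactly from a Hill model.
hill_curve <- function(v = 90, k = 2, n = 1.5,
                       doses = c(0, exp(seq(log(0.02), log(50),
                                            length.out = 14)))) {
  structure(data.frame(dose = doses,
                       inhibition = v * doses^n / (k^n + doses^n),
                       population = "average"),
            class = c("dose_response_curve", "data.frame"))
}
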