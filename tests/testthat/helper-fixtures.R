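# Shared fixtures built in code.

# Reference 23-sample dataset (both assays + printed labels + outcomes).
refSamples <- table3Fixture()

# Retrospective transfer cohort reconstructed from its published counts:
# 42 implanters (all below 0.003), 47 non-implanters of which 14 above.
retrospectiveCohort <- function() {
    data.frame(
        embryo_id = sprintf("R%02d", 1:89),
        value = c(rep(0.001, 42), rep(0.002, 33), rep(0.005, 14)),
        outcome = c(rep("implanted", 42), rep("not_implanted", 47)),
        stringsAsFactors = FALSE)
}

# Prospective cohort from its published counts: 15 above cutoff (none
# implanting), 27 below of which 16 implant.
prospectiveCohort <- function() {
    data.frame(
        embryo_id = sprintf("P%02d", 1:42),
        value = c(rep(0.005, 15), rep(0.001, 27)),
        outcome = c(rep("not_implanted", 15), rep("implanted", 16),
                    rep("not_implanted", 11)),
        stringsAsFactors = FALSE)
}

# Transfer-cohort generator settings: euploid blastocysts only, with the
# retrospective cohort's implantation rate.
transferConfig <- function(n = 89, seed = 1, ...) {
    simulationConfig(
        nEmbryos = n,
        aneuploidyRateByAge = stats::setNames(rep(0, 17), 26:42),
        implantationRate = 42 / 89, seed = seed, ...)
}

# Fully nulled generator: no age or ploidy effects and no
# outcome-coupling (infinite cutoff disables the viability truncation).
nullConfig <- function(n = 302, seed = 1) {
    simulationConfig(
        nEmbryos = n, blastocystAgeEffect = 1, cleavageAgeEffect = 1,
        aneuploidyEffect = 1, nonimplanterElevatedFraction = 0,
        viabilityCutoff = Inf, seed = seed)
}
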