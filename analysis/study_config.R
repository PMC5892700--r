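# Shared configuration for the analysis scripts: a deterministic scaled-down
# five-cohort study (~3,340 subjects, 20 phenotypes) with a small SNP panel
# covering the effect geometries of interest. Every script regenerates the
# study from this one seed, so the whole workflow is reproducible from text.

library(pleiometa)

STUDY_SEED <- 20180329L
RESULTS_DIR <- "results"

demo_snp_panel <- function() {
  list(
    # antagonistic: opposite effects on the positively correlated lipids
    effect_config("rs_ant1", 0.25,
                  c(TC = 0.22, TG = -0.22, HDLC = 0.18),
                  "antagonistic"),
    # antagonistic pair among blood-pressure markers
    effect_config("rs_ant2", 0.12, c(SBP = 0.3, DBP = -0.3),
                  "antagonistic"),
    # aligned effects of the same magnitude, for contrast
    effect_config("rs_ali1", 0.25, c(TC = 0.22, TG = 0.22, HDLC = 0.18),
                  "aligned"),
    # marker effect with strong inter-cohort heterogeneity
    effect_config("rs_het1", 0.3, c(BG = 0.25), "custom",
                  cohort_multipliers = c(ARIC = 1.6, CHS = 0.2, FHS = 1.0,
                                         MESA = 0.4, HRS = 1.3)),
    # risk-outcome effect (log-hazard units)
    effect_config("rs_out1", 0.2, c(CHD = 0.25, death = 0.2), "custom"),
    # nulls for calibration reference
    effect_config("rs_nul1", 0.3, pattern = "null"),
    effect_config("rs_nul2", 0.1, pattern = "null")
  )
}

make_demo_study <- function(seed = STUDY_SEED, scale = 0.1) {
  ph <- study_phenotypes(n_visits = 3)
  # exchangeable positive weak-to-modest correlation: with a sign-consistent
  # structure the injected aligned/antagonistic geometries mean what they say
  S <- make_phenotype_correlation(length(ph), strength = 0.25,
                                  method = "fixed")
  dimnames(S) <- list(names(ph), names(ph))
  simulate_study(study_cohorts(scale = scale), ph, S, demo_snp_panel(),
                 seed = seed)
}
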