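#!/usr/bin/env Rscript
# Stage 1 — simulate the two-sample study that the rest of the workflow
# analyses: a 60-variant LD block around a synthetic HMGCR region, an
# LDL-C-like exposure (10 causal variants), one molecular mediator on
# the exposure -> mediator -> outcome path, and a T2D-like binary
# outcome, with disjoint GWAS cohorts and a 494-sample LD reference
# panel. Individual-level sampling is used here so the emitted files
# are genuine marginal GWAS regressions; summary statistics go to
# results/simulated_study/ in COJO .ma format with the LD matrix and
# the ground-truth manifest alongside.

library(statinmr)

outdir <- "results/simulated_study"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_exposure_cohort = 30000L, n_outcome_cohort = 30000L,
  n_mediator_cohort = 20000L, n_ref_panel = 494L,
  causal_idx = seq(3L, 39L, by = 6L), theta_true = 0.2625,
  mediators = list(adrenic_acid = list(alpha = 0.35, beta = 0.25,
                                       own_idx = c(50L, 55L, 60L),
                                       own_effect = 0.15)),
  seed = 20260101L)

study <- simulate_two_sample_study(cfg, mode = "individual")

write_sumstats(study$exposure, file.path(outdir, "exposure_ldl.ma"))
write_sumstats(study$outcome, file.path(outdir, "outcome_t2d.ma"))
write_sumstats(study$mediators$adrenic_acid,
               file.path(outdir, "mediator_adrenic_acid.ma"))
write_ld(study$ld, file.path(outdir, "ld_reference.tsv"))
write_truth_manifest(study$truth, file.path(outdir, "truth_manifest.json"))

cat(sprintf("Simulated study written to %s\n", outdir))
cat(sprintf("  exposure SD: %.3f, regional h2: %.3f\n",
            study$truth$exposure_sd, study$truth$h2_exposure))
cat(sprintf("  true direct effect %.4f, total effect %.4f (log-OR per SD)\n",
            study$truth$theta_direct, study$truth$theta_total))
cat(sprintf("  planted mediation proportion: %.1f%%\n",
            study$truth$mediation_proportion))
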