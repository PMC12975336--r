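test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_exposure_cohort = 1000L, n_outcome_cohort = 1000L,
                    n_ref_panel = 200L, seed = 17)
  g1 <- simulate_genotypes(cfg, 500, "ref")
  g2 <- simulate_genotypes(cfg, 500, "ref")
  expect_identical(g1, g2)
  s1 <- simulate_two_sample_study(cfg, mode = "summary")
  s2 <- simulate_two_sample_study(cfg, mode = "summary")
  expect_identical(as.data.frame(s1$exposure), as.data.frame(s2$exposure))
  expect_identical(as.data.frame(s1$outcome), as.data.frame(s2$outcome))
  # different substreams decouple: another stream differs
  g3 <- simulate_genotypes(cfg, 500, "other")
  expect_false(identical(unname(g1), unname(g3)))
})

test_that("dosages are Hardy-Weinberg-consistent with the target frequency", {
  cfg <- sim_config(n_variants = 20L, maf_range = c(0.3, 0.3),
                    ld_model = list(type = "ar1", rho = 0), seed = 18)
  g <- simulate_genotypes(cfg, 50000, "hwe")
  freq <- colMeans(g) / 2
  expect_true(all(abs(freq - 0.3) < 0.01))
  # genotype-class proportions match HWE at the realized frequency
  p_hom <- colMeans(g == 2)
  expect_true(all(abs(p_hom - freq^2) < 0.01))
  # uncorrelated model: adjacent r2 is negligible
  r <- cor(g)
  expect_lt(max(r[cbind(1:19, 2:20)]^2), 0.01)
})

test_that("cohorts are disjoint and emitted datasets round-trip through io", {
  cfg <- sim_config(n_exposure_cohort = 800L, n_outcome_cohort = 700L,
                    n_mediator_cohort = 300L, n_ref_panel = 200L, seed = 19,
                    mediators = list(m1 = list(alpha = 0.3, beta = 0.2,
                                               own_idx = c(50L, 55L),
                                               own_effect = 0.15)))
  ge <- simulate_genotypes(cfg, cfg$n_exposure_cohort, "exposure")
  go <- simulate_genotypes(cfg, cfg$n_outcome_cohort, "outcome")
  expect_length(intersect(rownames(ge), rownames(go)), 0L)

  s <- simulate_two_sample_study(cfg, mode = "individual",
                                 binary_method = "linear")
  expect_named(s$mediators, "m1")
  path <- withr::local_tempfile(fileext = ".ma")
  write_sumstats(s$exposure, path)
  back <- read_sumstats(path, "cojo_ma", trait_id = "LDL")
  expect_equal(back$beta, s$exposure$beta, tolerance = 1e-6)
  expect_equal(back$pos, s$exposure$pos)
  # truth manifest serializes
  mpath <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(s$truth, mpath)
  truth <- jsonlite::read_json(mpath)
  expect_equal(truth$theta_total, s$truth$theta_total, tolerance = 1e-9)
})

test_that("realized marginal effects track the manifest's ground truth", {
  # near-constant allele frequencies keep the realized dosage LD at the
  # AR(1) target, so the manifest's marginal effects apply
  cfg <- sim_config(n_variants = 21L, causal_idx = 11L, gamma = 0.3,
                    maf_range = c(0.29, 0.31),
                    n_exposure_cohort = 30000L, n_outcome_cohort = 2000L,
                    n_ref_panel = 300L, theta_true = 0, seed = 20)
  s <- simulate_two_sample_study(cfg, mode = "individual",
                                 binary_method = "linear")
  # per-allele estimate back to the standardized-dosage scale
  ex <- as.data.frame(s$exposure)
  b_std_hat <- ex$beta * sqrt(2 * ex$eaf * (1 - ex$eaf))
  truth <- s$truth$marginal_std_exposure
  # lone causal variant: estimated standardized effect near gamma / sd_x
  ci <- which(s$truth$variant_keys == s$truth$causal_keys)
  expect_equal(unname(b_std_hat[ci]), unname(truth[ci]), tolerance = 0.05)
  expect_equal(unname(b_std_hat[ci]), 0.3 / s$truth$exposure_sd,
               tolerance = 0.05)
  # overall profile correlates strongly with the manifest
  expect_gt(cor(b_std_hat, truth), 0.95)
})

test_that("mediation bookkeeping composes the total effect", {
  cfg <- sim_config(theta_true = 0.2625,
                    causal_idx = seq(3L, 39L, by = 6L),
                    mediators = list(med = list(alpha = 0.35, beta = 0.25,
                                                own_idx = c(50L, 55L, 60L),
                                                own_effect = 0.15)),
                    seed = 21)
  s <- simulate_two_sample_study(cfg, mode = "summary")
  expect_equal(s$truth$theta_total, 0.2625 + 0.35 * 0.25)
  expect_equal(unname(s$truth$mediation_proportion), 25, tolerance = 1e-9)
  # over-specified mediator variance is rejected
  bad <- sim_config(mediators = list(m = list(alpha = 0.9, beta = 0.1,
                                              own_idx = 1:20,
                                              own_effect = 0.5)))
  expect_error(simulate_two_sample_study(bad, mode = "summary"),
               "unit variance")
})

test_that("coloc scenarios encode their sharing truth", {
  cfg <- sim_config(seed = 22)
  sh <- simulate_coloc_scenario("shared", cfg = cfg)
  expect_identical(sh$truth$causal1, sh$truth$causal2)
  di <- simulate_coloc_scenario("distinct", cfg = cfg, distinct_r2_bound = 0.01)
  r <- unclass(di$ld)
  expect_lt(r[di$truth$causal1, di$truth$causal2]^2, 0.01)
  nu <- simulate_coloc_scenario("null", cfg = cfg)
  expect_true(is.na(nu$truth$causal2))
  # an unattainable separation bound errors
  tight <- sim_config(n_variants = 5L, ld_model = list(type = "ar1", rho = 0.9))
  expect_error(simulate_coloc_scenario("distinct", cfg = tight,
                                       distinct_r2_bound = 1e-6),
               "bound")
})
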