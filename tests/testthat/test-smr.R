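test_that("the SMR statistic combines exposure and outcome z-scores", {
  s <- smr_test(z_x = 10, z_y = 5, beta_x = 0.2, beta_y = 0.1)
  expect_equal(s$t_smr, 100 * 25 / 125)  # = 20
  expect_equal(s$p_smr, pchisq(20, 1, lower.tail = FALSE))
  expect_equal(s$p_smr, 7.7e-6, tolerance = 0.01)
  expect_equal(s$b_smr, 0.5)
  s0 <- smr_test(10, 0)
  expect_equal(s0$t_smr, 0)
  expect_equal(s0$p_smr, 1)
  expect_error(smr_test(0, 5), "zero")
  # strong-instrument limit: the SMR p approaches the outcome Wald p
  # (the chi-square tail ratio is ~exp(zy^4 / (2 zx^2)), so the QTL
  # z-score must dominate zy^2 for tail agreement)
  for (zy in 1:5) {
    p_smr <- smr_test(300, zy)$p_smr
    p_wald <- 2 * pnorm(-zy)
    expect_lt(abs(p_smr - p_wald) / p_wald, 0.05)
  }
})

test_that("multi-SNP SMR reduces correctly and respects LD degrees of freedom", {
  # single qualifying SNP: identical to the single-SNP test
  inst <- make_instruments(c(0.3, 0.001), c(0.02, 0.02), c(0.1, 0.001),
                           c(0.02, 0.02))
  sm <- smr_multi(inst, p_qtl_threshold = 5e-8)
  expect_equal(sm$n_snps, 1L)
  s1 <- smr_test(0.3 / 0.02, 0.1 / 0.02)
  expect_equal(sm$p_smr_multi, s1$p_smr, tolerance = 1e-12)

  # duplicated SNP pair collapses to ~1 effective degree of freedom
  rho <- matrix(1, 2, 2)
  dup <- make_instruments(c(0.3, 0.3), c(0.02, 0.02), c(0.1, 0.1),
                          c(0.02, 0.02), rho = rho)
  sd2 <- smr_multi(dup, p_qtl_threshold = 5e-8, r2_prune = 1.01)
  expect_equal(sd2$n_snps, 2L)
  # T doubles but so does the Satterthwaite scale: p equals the 1-SNP p
  expect_equal(sd2$p_smr_multi, s1$p_smr, tolerance = 1e-8)

  expect_error(smr_multi(inst, p_qtl_threshold = 1e-300), "no QTL")
})

test_that("multi-SNP SMR is calibrated for independent QTLs", {
  set.seed(10)
  n_reps <- 3000; k <- 5
  zx <- rep(40, k)
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    zy <- rnorm(k)
    inst <- make_instruments(zx * 0.01, rep(0.01, k), zy * 0.01, rep(0.01, k))
    rej[r] <- smr_multi(inst, p_qtl_threshold = 5e-8)$p_smr_multi < 0.05
  }
  expect_equal(mean(rej), 0.05, tolerance = 0.015)
})

test_that("HEIDI is exact under identical Wald ratios and invariant to relabeling", {
  cfg <- sim_config(seed = 33)
  s <- simulate_two_sample_study(cfg, mode = "summary")
  inst <- instrument_set(harmonize(s$exposure, s$outcome), s$ld)

  # force identical ratios: outcome effects exactly proportional
  prop <- inst
  prop$beta_y <- 0.4 * prop$beta_x[, 1]
  h0 <- heidi_test(prop)
  expect_equal(h0$t_heidi, 0, tolerance = 1e-18)
  expect_equal(h0$p_heidi, 1)

  # relabeling non-top variants does not change the statistic
  h1 <- heidi_test(inst)
  perm <- c(seq_along(inst$variants))
  nontop <- setdiff(perm, match(h1$top_variant, inst$variants))
  perm[nontop] <- rev(nontop)
  h2 <- heidi_test(subset_instruments_for_test(inst, perm),
                   top_variant = h1$top_variant)
  expect_equal(h2$p_heidi, h1$p_heidi, tolerance = 1e-10)
  expect_equal(h2$n_used, h1$n_used)

  # no eligible partner variants: undefined, not an error
  lone <- make_instruments(c(0.3, 0.001), c(0.02, 0.02), c(0.1, 0.002),
                           c(0.02, 0.02))
  hl <- heidi_test(lone)
  expect_false(hl$defined)
  expect_true(is.na(hl$p_heidi))
})

test_that("HEIDI mostly passes when one causal variant truly drives both traits", {
  hh <- replicate_heidi_null(sim_config(seed = 2), n_reps = 60, seed = 40)
  expect_gte(mean(hh$p_heidi > 0.05, na.rm = TRUE), 0.85)
})

test_that("GSMR equals correlated IVW without outliers and removes planted ones", {
  set.seed(12)
  k <- 20
  bx <- runif(k, 0.1, 0.4)
  by <- 0.3 * bx + rnorm(k, 0, 0.01)
  inst <- make_instruments(bx, bx * 0.02, by, rep(0.01, k))
  g0 <- gsmr_estimate(inst, outlier_p = 0)
  i0 <- ivw_correlated(inst)
  expect_equal(g0$theta, i0$theta, tolerance = 1e-12)
  expect_equal(g0$method, "gsmr")

  # homogeneous data: nothing removed
  gh <- gsmr_estimate(inst)
  expect_length(attr(gh, "removed"), 0L)

  # one pleiotropic variant 5 SD off gets removed, estimate moves to truth
  by_out <- by; by_out[7] <- by[7] + 0.3
  inst_o <- make_instruments(bx, bx * 0.02, by_out, rep(0.01, k))
  go <- gsmr_estimate(inst_o)
  expect_true(inst$variants[7] %in% attr(go, "removed"))
  naive <- ivw_correlated(inst_o)
  expect_lt(abs(go$theta - 0.3), abs(naive$theta - 0.3))

  # single instrument reduces to the Wald ratio
  g1 <- gsmr_estimate(make_instruments(0.2, 0.01, 0.05, 0.01))
  w1 <- wald_ratio(0.2, 0.01, 0.05, 0.01)
  expect_equal(g1$theta, w1$theta)
  expect_equal(g1$se, w1$se)
})
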