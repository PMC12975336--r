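test_that("LD estimation matches brute-force Pearson correlation", {
  set.seed(42)
  n <- 200; m <- 8
  g <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(NULL, paste0("1:", 1:m)))
  ld <- ld_from_genotypes(g)
  # two-pass oracle
  oracle <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) {
    xi <- g[, i] - mean(g[, i]); xj <- g[, j] - mean(g[, j])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unclass(ld), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(ld, "n_ref"), n)

  # duplicated column gives r = 1
  g2 <- cbind(g, `1:9` = g[, 1])
  expect_equal(unname(unclass(ld_from_genotypes(g2))["1:1", "1:9"]), 1)

  # monomorphic variants are dropped; all-monomorphic errors
  g3 <- cbind(g, `1:10` = rep(2L, n))
  expect_message(ld3 <- ld_from_genotypes(g3), "monomorphic")
  expect_false("1:10" %in% rownames(ld3))
  expect_error(ld_from_genotypes(matrix(1, 10, 3,
                                        dimnames = list(NULL, paste0("1:", 1:3)))),
               "degenerate")
})

test_that("independent and AR(1)-correlated panels give the expected LD", {
  # independent variants: sampling bound |r| < 0.05 for 99% of pairs
  cfg0 <- sim_config(n_variants = 30L, ld_model = list(type = "ar1", rho = 0),
                     seed = 5)
  g0 <- simulate_genotypes(cfg0, 10000, "panel")
  r0 <- cor(g0)
  off <- abs(r0[upper.tri(r0)])
  expect_gte(mean(off < 0.05), 0.99)

  # AR(1) rho = 0.8 with comparable allele frequencies: adjacent pairs
  # average near the target
  cfg8 <- sim_config(n_variants = 40L, maf_range = c(0.3, 0.3), seed = 6)
  g8 <- simulate_genotypes(cfg8, 10000, "panel")
  r8 <- cor(g8)
  adj <- r8[cbind(1:39, 2:40)]
  expect_equal(mean(adj), 0.8, tolerance = 0.02)
})

test_that("PSD conditioning floors eigenvalues and keeps unit diagonal", {
  r <- matrix(c(1, 0.99, 0.1, 0.99, 1, 0.95, 0.1, 0.95, 1), 3, 3)
  dimnames(r) <- list(paste0("1:", 1:3), paste0("1:", 1:3))
  expect_lt(min(eigen(r, symmetric = TRUE)$values), 0)  # genuinely indefinite
  ld <- ld_matrix(r)
  expect_gte(min(eigen(unclass(ld), symmetric = TRUE)$values), -1e-8)
  expect_equal(unname(diag(unclass(ld))), rep(1, 3))
})

test_that("greedy clumping follows the hand-traced p-value ranking", {
  keys <- paste0("1:", c(100, 200, 300))
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.5)
  r[1, 3] <- r[3, 1] <- sqrt(0.1)
  r[2, 3] <- r[3, 2] <- sqrt(0.1)
  dimnames(r) <- list(keys, keys)
  ld <- ld_matrix(r)
  rec <- data.frame(chrom = "1", pos = c(100, 200, 300),
                    pvalue = c(1e-10, 1e-9, 1e-20))
  expect_equal(clump(rec, ld, p_max = 1e-8, r2_max = 0.3),
               c("1:300", "1:100"))
  # row order does not matter
  expect_equal(clump(rec[c(3, 1, 2), ], ld, p_max = 1e-8, r2_max = 0.3),
               c("1:300", "1:100"))
  # no LD: everything below p_max is kept
  ld_i <- ld_matrix(structure(diag(3), dimnames = list(keys, keys)))
  expect_length(clump(rec, ld_i, p_max = 1e-8, r2_max = 0.3), 3L)
  # nothing significant: empty result
  expect_length(clump(transform(rec, pvalue = 1e-3), ld, p_max = 1e-8), 0L)
})

test_that("every retained clump pair satisfies the r2 ceiling", {
  set.seed(11)
  for (rep in 1:5) {
    m <- 25
    keys <- paste0("1:", 1:m)
    g <- matrix(rnorm(400 * m), 400, m)
    g <- g + rnorm(400)  # induce correlation
    r <- cor(g); dimnames(r) <- list(keys, keys)
    ld <- ld_matrix(r)
    rec <- data.frame(chrom = "1", pos = 1:m, pvalue = runif(m, 1e-12, 1e-9))
    kept <- clump(rec, ld, p_max = 1e-8, r2_max = 0.2)
    if (length(kept) > 1) {
      sub <- unclass(ld)[kept, kept]
      expect_lt(max(sub[upper.tri(sub)]^2), 0.2)
    }
  }
})

test_that("gene-region instrument selection applies the drug-target filter tuple", {
  region <- gene_region_spec("HMGCR")
  expect_equal(region$window_bp, 1e6)  # +/-1000 kb default window
  cfg <- sim_config(seed = 8)
  s <- simulate_two_sample_study(cfg, mode = "summary")
  pairs <- harmonize(s$exposure, s$outcome)
  inst <- select_gene_region_instruments(pairs, region, s$ld)
  # a strongly causal variant is retained
  expect_gte(length(inst$variants), 1L)
  expect_true(any(inst$variants %in% s$truth$causal_keys))
  # exposure p-values of selected instruments all pass the threshold
  expect_lt(max(inst$p_x), 1e-8)
  # zero-width window with no variant at the TSS errors
  r0 <- gene_region_spec("HMGCR", chrom = cfg$chrom, tss = cfg$tss + 1,
                         window_bp = 1e-3)
  expect_error(select_gene_region_instruments(pairs, r0, s$ld),
               "no instrument")
  expect_error(gene_region_spec("NOSUCHGENE"), "no built-in")
})

test_that("per-SD-decrease scaling flips signs and is self-inverse", {
  inst <- make_instruments(beta_x = c(-0.2, 0.4), se_x = c(0.02, 0.02),
                           beta_y = c(0.1, 0.1), se_y = c(0.01, 0.01))
  s1 <- scale_to_sd_decrease(inst, 1)
  expect_equal(unname(s1$beta_x[, 1]), c(0.2, -0.4))
  s2 <- scale_to_sd_decrease(inst, 2)
  expect_equal(unname(s2$beta_x[, 1]), c(0.1, -0.2))
  expect_equal(unname(s2$se_x[, 1]), c(0.01, 0.01))
  expect_equal(scale_to_sd_decrease(s1, 1)$beta_x, inst$beta_x)
  expect_equal(s1$beta_y, inst$beta_y)  # outcome untouched
  expect_error(scale_to_sd_decrease(inst, 0), "positive")
})

test_that("outcome-associated instruments are removed with logging", {
  inst <- make_instruments(beta_x = c(0.2, 0.3, 0.25), se_x = rep(0.02, 3),
                           beta_y = c(0.001, 0.08, 0.002), se_y = rep(0.01, 3))
  # middle variant: |z_y| = 8 -> p ~ 1e-15 < 5e-8
  out <- drop_outcome_associated(inst)
  expect_equal(length(out$variants), 2L)
  expect_equal(attr(out, "removed"), inst$variants[2])
  # nothing significant: identity
  quiet <- make_instruments(beta_x = c(0.2, 0.3), se_x = rep(0.02, 2),
                            beta_y = c(0.001, 0.002), se_y = rep(0.01, 2))
  expect_equal(drop_outcome_associated(quiet)$variants, quiet$variants)
  # threshold 1 removes everything -> error
  expect_error(drop_outcome_associated(quiet, outcome_p_threshold = 1.1),
               "all instruments")
})

test_that("LD text round trip preserves the matrix", {
  r <- structure(diag(3) * 0.2 + 0.8, dimnames = list(paste0("1:", 1:3),
                                                      paste0("1:", 1:3)))
  diag(r) <- 1
  ld <- ld_matrix(r, n_ref = 494)
  path <- withr::local_tempfile()
  write_ld(ld, path)
  back <- read_ld(path, n_ref = 494)
  expect_equal(unclass(back), unclass(ld), tolerance = 1e-9)
})
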