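test_that("cojo_ma files parse, round-trip, and report rejected rows", {
  ds <- make_dataset(n = 6)
  path <- withr::local_tempfile(fileext = ".ma")
  write_sumstats(ds, path)
  back <- read_sumstats(path, "cojo_ma", trait_id = "trait")
  expect_equal(nrow(back), 6L)
  expect_equal(back$pos, ds$pos)
  expect_equal(back$beta, ds$beta, tolerance = 1e-6)
  expect_equal(back$se, ds$se, tolerance = 1e-6)
  expect_equal(back$effect_allele, ds$effect_allele)

  # one-record file: header + single data row
  one <- summary_dataset(make_sumstats_df(n = 1), "t1")
  p1 <- withr::local_tempfile()
  write_sumstats(one, p1)
  expect_length(readLines(p1), 2L)

  # se = 0 rows are dropped and counted; counts conserve
  df <- make_sumstats_df(n = 4)
  df$se[2] <- 0
  ds2 <- summary_dataset(df, "t2")
  rep <- load_report(ds2)
  expect_equal(nrow(ds2), 3L)
  expect_equal(rep$reasons$nonpositive_se, 1L)
  expect_equal(rep$rows_in, rep$rows_kept + rep$rows_rejected)
})

test_that("format errors are informative", {
  path <- withr::local_tempfile()
  writeLines(c("SNP A1 A2 freq b se N", "1:1 A G 0.3 0.1 0.01 1000"), path)
  expect_error(read_sumstats(path, "cojo_ma"), "p")
  empty <- withr::local_tempfile()
  file.create(empty)
  expect_error(read_sumstats(empty, "cojo_ma"), "empty")
  expect_error(write_sumstats(make_dataset(n = 2), "/nonexistent-dir/x/y.ma"),
               "could not write")
})

test_that("multi-allelic positions are dropped and p-values filled in", {
  df <- rbind(make_sumstats_df(n = 3),
              transform(make_sumstats_df(n = 1), effect_allele = "C"))
  ds <- summary_dataset(df, "t")
  expect_equal(nrow(ds), 2L)  # both records at the shared position go
  expect_equal(load_report(ds)$reasons$multiallelic, 2L)

  df2 <- make_sumstats_df(n = 2)
  df2$pvalue <- NA_real_
  ds2 <- summary_dataset(df2, "t")
  expect_equal(ds2$pvalue, 2 * pnorm(-abs(df2$beta / df2$se)))
})

test_that("harmonize aligns alleles, flips swapped codings, applies palindrome policy", {
  ex <- make_dataset(n = 4)
  # same coding: betas unchanged
  oy <- make_dataset(n = 4, beta = c(0.2, -0.1, 0.3, 0), trait_id = "out")
  h <- harmonize(ex, oy)
  expect_equal(h$beta_y, c(0.2, -0.1, 0.3, 0))

  # swapped alleles: sign flip and eaf complement
  df <- make_sumstats_df(n = 4, beta = c(0.2, -0.1, 0.3, 0), ea = "G", oa = "A")
  oy2 <- summary_dataset(df, "out")
  h2 <- harmonize(ex, oy2)
  expect_equal(h2$beta_y, -c(0.2, -0.1, 0.3, 0))
  expect_equal(h2$eaf_y, rep(0.7, 4))

  # A/T palindrome with eaf 0.5 is ambiguous under freq_infer(0.42)
  exp_p <- summary_dataset(make_sumstats_df(n = 2, ea = "A", oa = "T",
                                            eaf = c(0.5, 0.2)), "x")
  out_p <- summary_dataset(make_sumstats_df(n = 2, ea = "A", oa = "T",
                                            eaf = c(0.5, 0.2),
                                            beta = c(0.1, 0.2)), "y")
  hp <- harmonize(exp_p, out_p)
  expect_equal(nrow(hp), 1L)
  expect_equal(attr(hp, "harmonization_log")$palindromic_ambiguous, 1L)
  expect_equal(hp$beta_y, 0.2)
  # and drop policy removes them all
  expect_error(harmonize(exp_p, out_p, palindrome_policy = "drop"),
               NA)
  expect_equal(nrow(harmonize(exp_p, out_p, palindrome_policy = "drop")), 0L)

  # irreconcilable allele pairs are dropped and logged
  out_bad <- summary_dataset(make_sumstats_df(n = 4, ea = "C", oa = "A"), "y")
  hb <- harmonize(ex, out_bad)
  expect_equal(nrow(hb), 0L)
  expect_equal(attr(hb, "harmonization_log")$irreconcilable_alleles, 4L)

  expect_error(harmonize(ex, make_dataset(n = 2, start = 1L)), "overlap")
})

test_that("sign-flip involution: recoding every outcome record leaves pairs unchanged", {
  ex <- make_dataset(n = 5)
  oy <- make_dataset(n = 5, beta = c(0.2, -0.1, 0.3, 0, 0.05), trait_id = "out")
  h1 <- harmonize(ex, oy)
  flip <- as.data.frame(oy)
  flip[, c("effect_allele", "other_allele")] <- flip[, c("other_allele", "effect_allele")]
  flip$beta <- -flip$beta
  flip$eaf <- 1 - flip$eaf
  h2 <- harmonize(ex, summary_dataset(flip, "out"))
  expect_equal(h1$beta_y, h2$beta_y)
  expect_equal(h1$beta_x, h2$beta_x)
})

test_that("harmonization is idempotent on already-aligned data", {
  ex <- make_dataset(n = 5)
  oy <- make_dataset(n = 5, beta = seq(-0.1, 0.3, length.out = 5),
                     trait_id = "out")
  h1 <- harmonize(ex, oy)
  # rebuild an outcome dataset from the harmonized table and re-harmonize
  df <- data.frame(chrom = h1$chrom, pos = h1$pos, rsid = h1$rsid,
                   effect_allele = h1$effect_allele, other_allele = h1$other_allele,
                   eaf = h1$eaf_y, beta = h1$beta_y, se = h1$se_y,
                   pvalue = h1$p_y, n = h1$n_y, stringsAsFactors = FALSE)
  h2 <- harmonize(ex, summary_dataset(df, "out"))
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$eaf_y, h1$eaf_y)
})
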