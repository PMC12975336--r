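# Shared fixture builders: everything is generated in code at test time.

# Minimal well-formed association table over one LD block.
make_sumstats_df <- function(n = 6L, chrom = "5", start = 74632154L,
                             beta = NULL, se = NULL, eaf = NULL,
                             ea = "A", oa = "G") {
  pos <- start + (seq_len(n) - 1L) * 5000L
  beta <- beta %||% seq(0.05, by = 0.01, length.out = n)
  se <- se %||% rep(0.01, n)
  eaf <- eaf %||% rep(0.3, n)
  data.frame(chrom = chrom, pos = pos,
             rsid = paste(chrom, pos, sep = ":"),
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             eaf = eaf, beta = beta, se = se,
             pvalue = 2 * pnorm(-abs(beta / se)), n = 50000,
             stringsAsFactors = FALSE)
}

make_dataset <- function(..., trait_id = "trait", trait_type = "quantitative",
                         ancestry = "EAS") {
  summary_dataset(make_sumstats_df(...), trait_id = trait_id,
                  trait_type = trait_type, ancestry = ancestry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Identity-LD instrument set from raw effect vectors.
make_instruments <- function(beta_x, se_x, beta_y, se_y, rho = NULL,
                             outcome_type = "quantitative") {
  n <- length(beta_x)
  keys <- paste0("1:", seq_len(n) * 1000)
  rho <- rho %||% diag(n)
  dimnames(rho) <- list(keys, keys)
  pairs <- data.frame(chrom = "1", pos = seq_len(n) * 1000,
                      rsid = keys, effect_allele = "A", other_allele = "G",
                      eaf_x = 0.3, beta_x = beta_x, se_x = se_x,
                      p_x = 2 * pnorm(-abs(beta_x / se_x)), n_x = 1e5,
                      eaf_y = 0.3, beta_y = beta_y, se_y = se_y,
                      p_y = 2 * pnorm(-abs(beta_y / se_y)), n_y = 1e5,
                      stringsAsFactors = FALSE)
  attr(pairs, "outcome_type") <- outcome_type
  class(pairs) <- c("harmonized_pairs", "data.frame")
  instrument_set(pairs, ld_matrix(rho, n_ref = 500))
}

# Textbook (uncorrelated) inverse-variance-weighted ratio estimate: the
# independent oracle for identity-LD IVW.
textbook_ivw <- function(beta_x, beta_y, se_y) {
  w <- beta_x^2 / se_y^2
  theta_j <- beta_y / beta_x
  theta <- sum(w * theta_j) / sum(w)
  list(theta = theta, se = sqrt(1 / sum(w)))
}

# Reorder an instrument set's variants (for relabeling-invariance tests).
subset_instruments_for_test <- function(inst, ord) {
  inst$variants <- inst$variants[ord]
  inst$beta_x <- inst$beta_x[ord, , drop = FALSE]
  inst$se_x <- inst$se_x[ord, , drop = FALSE]
  inst$beta_y <- inst$beta_y[ord]
  inst$se_y <- inst$se_y[ord]
  inst$p_x <- inst$p_x[ord]
  inst$p_y <- inst$p_y[ord]
  inst$ld <- inst$ld[ord, ord]
  inst
}

# Brute-force colocalization oracle: explicit enumeration of all
# single-SNP and ordered SNP-pair causal configurations.
enumerate_coloc <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  n <- length(labf1)
  ab1 <- exp(labf1); ab2 <- exp(labf2)
  s0 <- 1
  s1 <- p1 * sum(ab1)
  s2 <- p2 * sum(ab2)
  s3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    s3 <- s3 + p1 * p2 * ab1[i] * ab2[j]
  s4 <- p12 * sum(ab1 * ab2)
  tot <- s0 + s1 + s2 + s3 + s4
  c(PP0 = s0, PP1 = s1, PP2 = s2, PP3 = s3, PP4 = s4) / tot
}
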