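# Summary-data-based MR (SMR), multi-SNP SMR, the HEIDI
# heterogeneity-in-dependent-instruments test, and a GSMR-style
# multi-instrument estimator with heterogeneity-outlier removal.

#' SMR test at a single QTL
#'
#' Combines the instrument's exposure and outcome z-statistics into
#' `T_SMR = z_x^2 z_y^2 / (z_x^2 + z_y^2)`, referred to a chi-square
#' with 1 df. The effect estimate is the Wald ratio at the top QTL with
#' delta-method SE `|b_smr| * sqrt(1/z_x^2 + 1/z_y^2)`.
#'
#' @param z_x,z_y exposure and outcome z-statistics (`z_x != 0`).
#' @param beta_x,beta_y optional effects for the Wald-ratio estimate.
#' @return list with `t_smr`, `p_smr`, and (when betas are supplied)
#'   `b_smr`, `se_smr`.
#' @export
smr_test <- function(z_x, z_y, beta_x = NULL, beta_y = NULL) {
  if (z_x == 0) stop("z_x is zero: SMR test undefined", call. = FALSE)
  t_smr <- z_x^2 * z_y^2 / (z_x^2 + z_y^2)
  out <- list(t_smr = t_smr,
              p_smr = stats::pchisq(t_smr, df = 1L, lower.tail = FALSE))
  if (!is.null(beta_x) && !is.null(beta_y)) {
    out$b_smr <- beta_y / beta_x
    out$se_smr <- abs(out$b_smr) * sqrt(1 / z_x^2 + 1 / z_y^2)
  }
  out
}

satterthwaite_p <- function(stat, lambda) {
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0L) return(NA_real_)
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  scale <- s2 / s1
  df <- s1^2 / s2
  stats::pchisq(stat / scale, df = df, lower.tail = FALSE)
}

smr_zx <- function(inst) inst$beta_x[, 1] / inst$se_x[, 1]
smr_zy <- function(inst) inst$beta_y / inst$se_y

#' Multi-SNP SMR test
#'
#' Sums the single-SNP SMR statistics of the strongest near-independent
#' QTLs in the region (greedy p-value-ranked selection with an r-squared
#' pruning ceiling, capped at `max_snps`). Because the per-SNP
#' statistics are correlated through LD, the null is a weighted sum of
#' 1-df chi-squares with weights taken as the eigenvalues of the
#' selected variants' LD correlation; the tail probability uses
#' two-moment (Satterthwaite) matching.
#'
#' @param instruments an [instrument_set()] over the region, exposure =
#'   the molecular trait.
#' @param p_qtl_threshold QTL inclusion threshold on the exposure p.
#' @param max_snps cap on the number of QTLs pooled (default 10).
#' @param r2_prune pruning ceiling between selected QTLs (default 0.9).
#' @return list with `t_multi`, `p_smr_multi`, `n_snps`, `snps`.
#' @export
smr_multi <- function(instruments, p_qtl_threshold = 5e-8, max_snps = 10L,
                      r2_prune = 0.9) {
  zx <- smr_zx(instruments); zy <- smr_zy(instruments)
  p_x <- 2 * stats::pnorm(-abs(zx))
  elig <- which(p_x < p_qtl_threshold & zx != 0)
  if (length(elig) == 0L)
    stop("no QTL passes p < ", format(p_qtl_threshold), call. = FALSE)
  ord <- elig[order(p_x[elig])]
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= max_snps) break
    if (all(instruments$ld[i, sel]^2 < r2_prune)) sel <- c(sel, i)
  }
  t_i <- zx[sel]^2 * zy[sel]^2 / (zx[sel]^2 + zy[sel]^2)
  t_multi <- sum(t_i)
  lambda <- eigen(instruments$ld[sel, sel, drop = FALSE], symmetric = TRUE,
                  only.values = TRUE)$values
  list(t_multi = t_multi, p_smr_multi = satterthwaite_p(t_multi, lambda),
       n_snps = length(sel), snps = instruments$variants[sel])
}

# Wald-ratio variance and pairwise covariance used by HEIDI and the
# GSMR outlier filter: var(b_i) ~ se_y_i^2/bx_i^2 + b_ref^2 se_x_i^2/bx_i^2,
# cov(b_i, b_j) built from the LD correlation on both trait sides.
wald_cov <- function(inst, b_ref) {
  bx <- inst$beta_x[, 1]; sx <- inst$se_x[, 1]; sy <- inst$se_y
  rho <- inst$ld
  (rho * outer(sy, sy) + b_ref^2 * rho * outer(sx, sx)) / outer(bx, bx)
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Under a single causal variant shared by the molecular trait and the
#' outcome, the Wald ratio at every variant in LD with the top QTL
#' estimates the same quantity; HEIDI tests the deviations
#' `d_i = b_i - b_top` jointly. A small p-value rejects the
#' single-shared-variant model (linkage rather than causality or
#' pleiotropy); the screen's pass rule is `p_heidi > 0.05`.
#'
#' Eligible variants have QTL p below `qtl_p_max` and r-squared with the
#' top QTL inside `r2_window`, capped at the `max_snps` strongest. The
#' statistic `sum(d_i^2 / var(d_i))` is referred to a weighted
#' chi-square null (eigenvalues of the deviations' correlation matrix,
#' two-moment tail matching), with the delta-method variances and
#' LD-derived covariances of the Wald ratios.
#'
#' @param instruments region [instrument_set()].
#' @param top_variant key of the top QTL; defaults to the largest
#'   `|z_x|`.
#' @param r2_window eligible r-squared range with the top QTL.
#' @param max_snps cap on eligible variants (default 20).
#' @param qtl_p_max QTL significance ceiling for eligibility.
#' @return list with `p_heidi`, `n_used`, `defined`, `top_variant`.
#' @export
heidi_test <- function(instruments, top_variant = NULL,
                       r2_window = c(0.05, 0.9), max_snps = 20L,
                       qtl_p_max = 1.57e-3) {
  zx <- smr_zx(instruments)
  if (is.null(top_variant)) top_variant <- instruments$variants[which.max(abs(zx))]
  ti <- match(top_variant, instruments$variants)
  if (is.na(ti)) stop("top_variant not in the instrument set", call. = FALSE)
  r2 <- instruments$ld[ti, ]^2
  p_x <- 2 * stats::pnorm(-abs(zx))
  elig <- which(p_x < qtl_p_max & r2 >= r2_window[1] & r2 <= r2_window[2] &
                  seq_along(zx) != ti)
  if (length(elig) == 0L)
    return(list(p_heidi = NA_real_, n_used = 0L, defined = FALSE,
                top_variant = top_variant))
  if (length(elig) > max_snps) elig <- elig[order(-abs(zx[elig]))][seq_len(max_snps)]

  idx <- c(ti, elig)
  sub <- subset_instruments(instruments, idx)
  b <- sub$beta_y / sub$beta_x[, 1]
  cv <- wald_cov(sub, b_ref = b[1])
  k <- length(b) - 1L
  # cov(d_i, d_j) with d_i = b_i - b_top (top is entry 1)
  cd <- cv[-1, -1, drop = FALSE] -
    matrix(cv[-1, 1], k, k) - matrix(cv[1, -1], k, k, byrow = TRUE) + cv[1, 1]
  d <- b[-1] - b[1]
  vd <- diag(cd)
  stat <- sum(d^2 / vd)
  corr_d <- stats::cov2cor((cd + t(cd)) / 2)
  lambda <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  list(p_heidi = satterthwaite_p(stat, lambda), n_used = k, defined = TRUE,
       top_variant = top_variant, t_heidi = stat)
}

#' GSMR-style estimator with heterogeneity-outlier removal
#'
#' Multi-instrument summary-data MR for approximately independent
#' instruments (clumped at r-squared < 0.05, P < 5e-8 for reverse-MR
#' use): iteratively removes instruments whose single-SNP Wald estimate
#' deviates from the pooled correlated-IVW estimate at `p < outlier_p`
#' (the HEIDI-outlier step against pleiotropic variants), then returns
#' the correlated-IVW fit on the survivors. `outlier_p = 0` disables
#' removal, making the result identical to [ivw_correlated()].
#'
#' @param instruments an [instrument_set()].
#' @param outlier_p outlier removal threshold (default 0.01).
#' @param model variance model passed to [ivw_correlated()].
#' @param max_iter iteration cap.
#' @return an `mr_estimate` with method `"gsmr"`; attribute
#'   `"removed"` lists excluded variant keys.
#' @export
gsmr_estimate <- function(instruments, outlier_p = 0.01,
                          model = c("default", "fixed", "multiplicative_random"),
                          max_iter = 20L) {
  model <- match.arg(model)
  inst <- instruments
  removed <- character(0)
  for (it in seq_len(max_iter)) {
    fit <- ivw_correlated(inst, model = model)
    if (outlier_p <= 0 || n_instruments(inst) <= 1L) break
    # deviation test against the fixed-effect pooled estimate: var(d_i)
    # ~ var(b_i) - var(theta_hat), floored at var(b_i)/2 so a strongly
    # heterogeneous interim fit cannot flag every instrument
    pooled <- ivw_correlated(inst, model = "fixed")
    b <- inst$beta_y / inst$beta_x[, 1]
    vb <- diag(wald_cov(inst, b_ref = pooled$theta))
    vd <- pmax(vb - pooled$se^2, vb / 2)
    p_dev <- stats::pchisq((b - pooled$theta)^2 / vd, df = 1L, lower.tail = FALSE)
    worst <- which.min(p_dev)
    if (p_dev[worst] >= outlier_p) break
    if (n_instruments(inst) == 1L)
      stop("all instruments flagged as heterogeneity outliers", call. = FALSE)
    removed <- c(removed, inst$variants[worst])
    inst <- subset_instruments(inst, -worst)
  }
  fit$method <- "gsmr"
  attr(fit, "removed") <- removed
  fit
}
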