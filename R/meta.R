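# Cross-ancestry fixed-effect meta-analysis, mediation by the product
# of coefficients, and grouped Benjamini-Hochberg FDR.

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-study estimates (log-odds scale for binary outcomes) by
#' inverse-variance weighting: `theta = sum(w_i theta_i) / sum(w_i)`
#' with `w_i = 1/se_i^2` and `se = sum(w_i)^{-1/2}`. Heterogeneity is
#' summarized by the meta-analytic Q and `I^2 = max(0, (Q - df)/Q)`.
#'
#' @param theta numeric vector of per-study estimates.
#' @param se matching standard errors (all positive).
#' @return a `meta_result` list: `theta_meta`, `se_meta`, `ci_low`,
#'   `ci_high`, `pvalue`, `q_meta`, `i2`, `k`, and the inputs.
#' @export
fixed_effect_meta <- function(theta, se) {
  if (length(theta) == 0L) stop("no estimates to pool", call. = FALSE)
  if (length(theta) != length(se)) stop("theta and se lengths differ", call. = FALSE)
  if (any(!is.finite(se) | se <= 0)) stop("all standard errors must be positive", call. = FALSE)
  w <- 1 / se^2
  tm <- sum(w * theta) / sum(w)
  sm <- sqrt(1 / sum(w))
  q <- sum(w * (theta - tm)^2)
  df <- length(theta) - 1L
  i2 <- if (df > 0 && q > 0) max(0, (q - df) / q) else 0
  structure(list(theta_meta = tm, se_meta = sm,
                 ci_low = tm - Z95 * sm, ci_high = tm + Z95 * sm,
                 pvalue = 2 * stats::pnorm(-abs(tm / sm)),
                 q_meta = q,
                 q_pvalue = if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_,
                 i2 = i2, k = length(theta), theta_i = theta, se_i = se),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effect meta (k = %d): theta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, I2 = %.1f%%\n",
              x$k, x$theta_meta, x$se_meta, x$ci_low, x$ci_high, x$pvalue, 100 * x$i2))
  invisible(x)
}

#' Recover a standard error from a 95% confidence interval
#'
#' `(high - low) / (2 * 1.959964)`, for reconstructing log-OR standard
#' errors from published odds ratios with their confidence bounds.
#'
#' @param low,high interval bounds on the estimate's own (e.g. log-OR)
#'   scale, `high > low`.
#' @return the implied standard error.
#' @export
ci_to_se <- function(low, high) {
  if (any(high <= low)) stop("ci_to_se: high bound must exceed low bound", call. = FALSE)
  (high - low) / (2 * Z95)
}

#' Meta-analyse published odds ratios
#'
#' Convenience wrapper: converts per-study `(OR, ci_low, ci_high)`
#' triplets to the log scale via [ci_to_se()] and pools with
#' [fixed_effect_meta()]. The returned list carries the pooled OR and
#' its CI alongside the log-scale meta result.
#'
#' @param or,ci_low,ci_high per-study odds ratios and 95% bounds.
#' @return a `meta_result` with extra elements `or_meta`, `or_ci_low`,
#'   `or_ci_high`.
#' @export
meta_from_or <- function(or, ci_low, ci_high) {
  res <- fixed_effect_meta(log(or), ci_to_se(log(ci_low), log(ci_high)))
  res$or_meta <- exp(res$theta_meta)
  res$or_ci_low <- exp(res$ci_low)
  res$or_ci_high <- exp(res$ci_high)
  res
}

#' Mediation by the product of coefficients
#'
#' Indirect effect `alpha * beta`, where `alpha` is the drug-target
#' (exposure) effect on the mediator and `beta` the mediator's effect on
#' the outcome adjusted for the drug target. The standard error of the
#' product is `sqrt(alpha^2 se_beta^2 + beta^2 se_alpha^2 -
#' se_alpha^2 se_beta^2)`; this unbiased-variance form can go negative
#' when both coefficients are near zero, in which case the first-order
#' delta SE `sqrt(alpha^2 se_beta^2 + beta^2 se_alpha^2)` is used and
#' flagged (`se_fallback = TRUE`).
#'
#' The proportion mediated is `indirect / total`, with `total` the total
#' drug-target effect on the outcome from univariable MR; it is reported
#' as a percentage and flagged undefined when `|total|` is below
#' tolerance.
#'
#' @param alpha,se_alpha exposure-to-mediator effect and SE.
#' @param beta,se_beta mediator-to-outcome (adjusted) effect and SE.
#' @param total,se_total total exposure-to-outcome effect and SE.
#' @return a `mediation_result` list.
#' @export
mediation_product <- function(alpha, se_alpha, beta, se_beta,
                              total = NA_real_, se_total = NA_real_) {
  if (se_alpha <= 0 || se_beta <= 0)
    stop("coefficient standard errors must be positive", call. = FALSE)
  if (!is.na(se_total) && se_total <= 0)
    stop("se_total must be positive", call. = FALSE)
  indirect <- alpha * beta
  operand <- alpha^2 * se_beta^2 + beta^2 * se_alpha^2 - se_alpha^2 * se_beta^2
  fallback <- operand < 0
  se_indirect <- if (fallback)
    sqrt(alpha^2 * se_beta^2 + beta^2 * se_alpha^2) else sqrt(operand)
  undefined <- is.na(total) || abs(total) < 1e-12
  prop <- if (undefined) NA_real_ else 100 * indirect / total
  z <- indirect / se_indirect
  structure(list(alpha = alpha, se_alpha = se_alpha,
                 beta = beta, se_beta = se_beta,
                 indirect = indirect, se_indirect = se_indirect,
                 se_fallback = fallback,
                 pvalue_indirect = if (se_indirect > 0) 2 * stats::pnorm(-abs(z)) else NA_real_,
                 total = total, se_total = se_total,
                 proportion_mediated = prop,
                 proportion_undefined = undefined),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: indirect = %.4f (SE %.4f%s)",
              x$indirect, x$se_indirect,
              if (x$se_fallback) ", delta fallback" else ""))
  if (!x$proportion_undefined)
    cat(sprintf("; proportion mediated = %.1f%%", x$proportion_mediated))
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR within feature families
#'
#' Applies the BH step-up procedure independently within each group —
#' for omics screens, one family per microbial taxonomic rank and one
#' each for metabolites and proteins, so that correction strength
#' matches the feature family's multiplicity.
#'
#' @param pvalues numeric p-values in `(0, 1]`.
#' @param groups grouping factor (single group when `NULL`).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, length(pvalues))
  if (length(groups) != length(pvalues)) stop("groups length mismatch", call. = FALSE)
  q <- rep(NA_real_, length(pvalues))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    q[idx] <- stats::p.adjust(pvalues[idx], method = "BH")
  }
  q
}
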