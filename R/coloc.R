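# Approximate-Bayes-factor colocalization of two traits over a gene
# region, under the single-causal-variant-per-trait assumption.

#' Wakefield log approximate Bayes factor
#'
#' For a variant with estimate `beta`, standard error `se`, and a
#' zero-mean normal effect prior with SD `prior_sd`:
#' `lABF = 0.5 * log(V/(V+W)) + 0.5 * (W/(V+W)) * Z^2` with `V = se^2`,
#' `W = prior_sd^2`, `Z = beta/se`.
#'
#' @param beta,se association estimate and standard error (`se > 0`).
#' @param prior_sd prior effect SD (`> 0`); conventionally 0.15 for
#'   quantitative traits and 0.2 for binary (log-odds) traits.
#' @return log ABF (vectorized over `beta`/`se`).
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (prior_sd <= 0) stop("prior_sd must be positive", call. = FALSE)
  v <- se^2
  w <- prior_sd^2
  r <- w / (v + w)
  0.5 * log(1 - r) + 0.5 * r * (beta / se)^2
}

default_prior_sd <- function(trait_type) {
  if (identical(trait_type, "binary")) 0.2 else 0.15
}

#' Approximate-Bayes-factor colocalization
#'
#' Tests whether two traits share a single causal variant in a region by
#' enumerating the five sharing hypotheses: H0 no association, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4
#' one shared causal variant. Per-SNP log-ABFs are combined with
#' log-sum-exp stabilization; the H3 sum over ordered distinct pairs is
#' obtained as the full product sum minus the shared-SNP diagonal.
#' Hypothesis sums are weighted by the priors `p1`, `p2` (per-SNP
#' association with each single trait) and `p12` (per-SNP association
#' with both).
#'
#' Inputs are either two [summary_dataset()]s (harmonized internally and
#' optionally restricted to a [gene_region_spec()]) or a pre-harmonized
#' pair table from [harmonize()].
#'
#' @param trait1,trait2 `summary_dataset`s for the two traits, or pass a
#'   `harmonized_pairs` table as `trait1`.
#' @param region optional [gene_region_spec()]; variants outside
#'   `tss +/- window_bp` are excluded.
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd1,prior_sd2 effect-prior SDs; default chosen from each
#'   trait's type (0.15 quantitative, 0.2 binary).
#' @return a `coloc_result`: posteriors `pp` (PP0..PP4), per-SNP
#'   log-ABFs, `n_snps`, and the priors used.
#' @export
coloc_abf <- function(trait1, trait2 = NULL, region = NULL,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  if (inherits(trait1, "harmonized_pairs")) {
    pairs <- trait1
    prior_sd1 <- prior_sd1 %||% 0.15
    prior_sd2 <- prior_sd2 %||% default_prior_sd(attr(pairs, "outcome_type"))
  } else {
    prior_sd1 <- prior_sd1 %||% default_prior_sd(attr(trait1, "trait_type"))
    prior_sd2 <- prior_sd2 %||% default_prior_sd(attr(trait2, "trait_type"))
    pairs <- harmonize(trait1, trait2)
  }
  df <- as.data.frame(pairs)
  if (!is.null(region))
    df <- df[df$chrom == region$chrom & abs(df$pos - region$tss) <= region$window_bp, ]
  if (nrow(df) == 0L) stop("no shared variants in the region", call. = FALSE)

  l1 <- log_abf(df$beta_x, df$se_x, prior_sd1)
  l2 <- log_abf(df$beta_y, df$se_y, prior_sd2)
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  lh3 <- if (nrow(df) == 1L) -Inf else logdiffexp(lsum1 + lsum2, lsum12)

  lpost <- c(h0 = 0,
             h1 = log(p1) + lsum1,
             h2 = log(p2) + lsum2,
             h3 = log(p1) + log(p2) + lh3,
             h4 = log(p12) + lsum12)
  denom <- logsumexp(lpost)
  pp <- exp(lpost - denom)
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, labf1 = l1, labf2 = l2,
                 snp = position_key(df$chrom, df$pos), n_snps = nrow(df),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = c(trait1 = prior_sd1, trait2 = prior_sd2)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d SNP(s):\n", x$n_snps))
  print(round(x$pp, 4))
  invisible(x)
}

#' Two-panel regional association plot
#'
#' The standard colocalization figure: -log10 p-values against position
#' for both traits over the region, top variants highlighted. Writes
#' SVG or PNG when `file` is given (by extension), otherwise draws on
#' the active device.
#'
#' @param pairs a [harmonize()]d pair table covering the region.
#' @param region optional [gene_region_spec()] used to restrict and
#'   annotate the panel.
#' @param file optional output path ending in `.svg` or `.png`.
#' @param labels character pair naming the traits.
#' @return the input, invisibly.
#' @export
plot_coloc_region <- function(pairs, region = NULL, file = NULL,
                              labels = c(attr(pairs, "exposure_id") %||% "trait 1",
                                         attr(pairs, "outcome_id") %||% "trait 2")) {
  df <- as.data.frame(pairs)
  if (!is.null(region))
    df <- df[df$chrom == region$chrom & abs(df$pos - region$tss) <= region$window_bp, ]
  if (nrow(df) == 0L) stop("no variants to plot in the region", call. = FALSE)
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 6)
    else grDevices::png(file, width = 1400, height = 1200, res = 200)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  lp1 <- -stats::pnorm(-abs(df$beta_x / df$se_x), log.p = TRUE) / log(10) - log10(2)
  lp2 <- -stats::pnorm(-abs(df$beta_y / df$se_y), log.p = TRUE) / log(10) - log10(2)
  mb <- df$pos / 1e6
  old <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (panel in 1:2) {
    lp <- if (panel == 1) lp1 else lp2
    graphics::plot(mb, lp, pch = 16, col = "grey40",
                   xlab = if (panel == 2) sprintf("chr%s position (Mb)", df$chrom[1]) else "",
                   ylab = expression(-log[10](p)), main = labels[panel])
    top <- which.max(lp)
    graphics::points(mb[top], lp[top], pch = 18, col = "purple", cex = 1.6)
    if (!is.null(region)) graphics::abline(v = region$tss / 1e6, lty = 3)
  }
  invisible(pairs)
}

#' Colocalization decision rule
#'
#' Declares colocalization when the shared-causal-variant posterior
#' strictly exceeds the threshold (`PP4 > 0.7` by default).
#'
#' @param result a `coloc_result`.
#' @param pp4_threshold decision threshold.
#' @return `"colocalized"` or `"not_colocalized"`.
#' @export
classify_coloc <- function(result, pp4_threshold = 0.7) {
  if (result$pp["PP4"] > pp4_threshold) "colocalized" else "not_colocalized"
}
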