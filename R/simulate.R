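# Synthetic two-sample GWAS generator with known ground truth.
#
# The generator emulates the statistical structure of a drug-target MR
# study: one LD block containing a designated drug-target gene region,
# a heritable quantitative exposure (LDL-C-like) driven by several
# causal variants in the region, optional molecular mediators on the
# exposure -> mediator -> outcome path, and a binary liability-threshold
# outcome (T2D-like). Exposure, mediator, outcome and LD-reference
# cohorts are disjoint by construction (the two-/three-sample design).
#
# Two sampling modes are provided. "individual" draws Hardy-Weinberg
# 0/1/2 dosages from a latent-Gaussian haplotype model whose latent
# correlations are calibrated so realized dosage LD matches the target,
# measures phenotypes per person, and runs per-variant marginal
# regressions. "summary" samples the marginal association estimates
# directly from their asymptotic distribution (estimates ~ MVN with LD-
# structured covariance around the true marginal effects), which makes
# thousand-replicate calibration studies cheap while preserving the
# quantities every estimator consumes.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic two-sample GWAS.
#' Defaults describe a single 60-variant LD block (AR(1) dosage
#' correlation 0.8, spacing 5 kb) centered on a synthetic drug-target
#' gene, with 10 causal variants of equal weight explaining roughly a
#' quarter of exposure variance, 50,000 individuals per GWAS arm, a
#' 494-sample LD reference panel, causal effect `theta_true = 0.35`
#' (log-odds per SD exposure) and outcome prevalence 10%.
#'
#' @param n_variants number of variants in the block.
#' @param ld_model list: `list(type = "ar1", rho = )` or
#'   `list(type = "block", size = , rho = )` (independent blocks with
#'   constant within-block dosage correlation).
#' @param maf_range minor-allele-frequency range, within `(0, 0.5]`.
#' @param n_exposure_cohort,n_outcome_cohort,n_mediator_cohort,n_ref_panel
#'   cohort sizes (all disjoint).
#' @param causal_idx indices of exposure-causal variants; `NULL` spreads
#'   up to 10 causal variants evenly across the block.
#' @param gamma causal effects per standardized dosage (recycled).
#' @param exposure_noise_sd non-genetic exposure SD.
#' @param theta_true direct exposure effect on the outcome liability /
#'   log-odds scale, per SD of exposure.
#' @param mediators named list; each element
#'   `list(alpha =, beta =, own_idx =, own_effect =)` gives the
#'   exposure-to-mediator effect (SD of mediator per SD exposure), the
#'   mediator-to-outcome effect, and the mediator's own causal variants.
#'   The total exposure effect is then `theta_true + sum(alpha * beta)`.
#' @param prevalence outcome case fraction, in `(0, 1)`.
#' @param gene_id,chrom,tss,spacing_bp region layout of the block.
#' @param seed master seed; stages derive named substreams from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_variants = 60L,
                       ld_model = list(type = "ar1", rho = 0.8),
                       maf_range = c(0.1, 0.5),
                       n_exposure_cohort = 50000L,
                       n_outcome_cohort = 50000L,
                       n_mediator_cohort = 50000L,
                       n_ref_panel = 494L,
                       causal_idx = NULL,
                       gamma = 0.15,
                       exposure_noise_sd = 1,
                       theta_true = 0.35,
                       mediators = list(),
                       prevalence = 0.1,
                       gene_id = "HMGCR",
                       chrom = "5",
                       tss = 74632154,
                       spacing_bp = 5000,
                       seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)", call. = FALSE)
  if (any(maf_range <= 0) || any(maf_range > 0.5)) stop("maf_range must be within (0, 0.5]", call. = FALSE)
  if (is.null(causal_idx))
    causal_idx <- unique(pmin(as.integer(n_variants),
                              pmax(1L, round(seq(0.05, 0.95,
                                                 length.out = min(10L, n_variants)) *
                                               n_variants))))
  if (any(causal_idx > n_variants)) stop("causal_idx outside the block", call. = FALSE)
  cfg <- list(n_variants = as.integer(n_variants), ld_model = ld_model,
              maf_range = maf_range,
              n_exposure_cohort = as.integer(n_exposure_cohort),
              n_outcome_cohort = as.integer(n_outcome_cohort),
              n_mediator_cohort = as.integer(n_mediator_cohort),
              n_ref_panel = as.integer(n_ref_panel),
              causal_idx = as.integer(causal_idx),
              gamma = rep_len(gamma, length(causal_idx)),
              exposure_noise_sd = exposure_noise_sd,
              theta_true = theta_true, mediators = mediators,
              prevalence = prevalence, gene_id = gene_id, chrom = chrom,
              tss = tss, spacing_bp = spacing_bp, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

sim_positions <- function(cfg) {
  j <- seq_len(cfg$n_variants)
  round(cfg$tss + (j - (cfg$n_variants + 1) / 2) * cfg$spacing_bp)
}

sim_keys <- function(cfg) position_key(cfg$chrom, sim_positions(cfg))

sim_mafs <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "panel"))
  stats::runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])
}

# Target dosage correlation matrix implied by the LD model.
sim_target_ld <- function(cfg) {
  m <- cfg$n_variants
  if (cfg$ld_model$type == "ar1") {
    r <- cfg$ld_model$rho^abs(outer(seq_len(m), seq_len(m), `-`))
  } else if (cfg$ld_model$type == "block") {
    size <- cfg$ld_model$size
    blk <- (seq_len(m) - 1L) %/% size
    r <- ifelse(outer(blk, blk, `==`), cfg$ld_model$rho, 0)
    diag(r) <- 1
  } else stop("unknown ld_model type", call. = FALSE)
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("ld_model implies a non-PSD correlation target", call. = FALSE)
  dimnames(r) <- list(sim_keys(cfg), sim_keys(cfg))
  r
}

# Centered bivariate-normal orthant term via the tetrachoric (Hermite)
# series: cov(1{Z1<t1}, 1{Z2<t2}) as a function of the latent
# correlation a, using normalized Hermite polynomials for stability.
hermite_basis <- function(t, k_max) {
  h <- numeric(k_max)
  h[1] <- 1
  if (k_max >= 2L) h[2] <- t
  for (k in 3:k_max)
    h[k] <- (t * h[k - 1L] - sqrt(k - 2) * h[k - 2L]) / sqrt(k - 1)
  h * stats::dnorm(t)
}

indicator_cov <- function(a, g1, g2) {
  k <- seq_along(g1)
  sum(a^k * g1 * g2 / k)
}

# Latent correlation that makes two thresholded haplotype indicators
# (allele frequencies f1, f2) correlate at the target dosage LD level.
# Targets beyond the attainable (Frechet) bound are capped near 1.
solve_latent_corr <- function(r_target, f1, f2, k_max = 120L) {
  if (abs(r_target) < 1e-10) return(0)
  cov_target <- r_target * sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  g1 <- hermite_basis(stats::qnorm(f1), k_max)
  g2 <- hermite_basis(stats::qnorm(f2), k_max)
  g <- function(a) indicator_cov(a, g1, g2) - cov_target
  if (g(0.999) < 0) return(0.999)
  if (g(-0.999) > 0) return(-0.999)
  stats::uniroot(g, c(-0.999, 0.999), tol = 1e-9)$root
}

# Latent haplotype correlation matrix: every pair calibrated so the
# thresholded dosages reproduce the target LD at all distances, then
# PSD-conditioned and factored for sampling. Cached per configuration.
latent_cache <- new.env(parent = emptyenv())

sim_latent_chol <- function(cfg, mafs) {
  key <- paste(cfg$seed, cfg$n_variants, cfg$ld_model$type,
               cfg$ld_model$rho, cfg$ld_model$size %||% 0,
               signif(cfg$maf_range[1], 8), signif(cfg$maf_range[2], 8),
               sep = "_")
  if (!is.null(latent_cache[[key]])) return(latent_cache[[key]])
  r_target <- unname(sim_target_ld(cfg))
  m <- cfg$n_variants
  lat <- diag(m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (abs(r_target[i, j]) > 1e-8)
      lat[i, j] <- lat[j, i] <- solve_latent_corr(r_target[i, j],
                                                  mafs[i], mafs[j])
  }
  ch <- chol(condition_psd(lat, floor = 1e-8))
  latent_cache[[key]] <- ch
  ch
}

sample_haplotypes <- function(n, mafs, lat_chol) {
  m <- length(mafs)
  z <- matrix(stats::rnorm(n * m), n, m) %*% lat_chol
  t(t(z) < stats::qnorm(mafs)) * 1L
}

#' Simulate reference-panel and cohort genotypes
#'
#' Draws Hardy-Weinberg-consistent 0/1/2 dosages: each of the two
#' haplotypes is a thresholded latent Gaussian whose correlation
#' structure is calibrated (variant pair by variant pair) so the
#' *dosage* correlations match the configured LD target. Identical
#' seeds give identical output.
#'
#' @param cfg a [sim_config()].
#' @param n number of individuals.
#' @param stream substream name entering the seed derivation.
#' @return integer dosage matrix, individuals x variants, variant keys
#'   as column names and `<stream>_<i>` sample IDs as row names.
#' @export
simulate_genotypes <- function(cfg, n, stream = "ref") {
  mafs <- sim_mafs(cfg)
  lat_chol <- sim_latent_chol(cfg, mafs)
  set.seed(substream_seed(cfg$seed, paste0("geno_", stream)))
  g <- sample_haplotypes(n, mafs, lat_chol) + sample_haplotypes(n, mafs, lat_chol)
  dimnames(g) <- list(paste0(stream, "_", seq_len(n)), sim_keys(cfg))
  g
}

# Fast per-variant marginal linear regression; returns per-allele
# estimates, SEs and p-values.
marginal_lm <- function(g, y) {
  n <- length(y)
  gm <- colMeans(g)
  gc <- sweep(g, 2L, gm)
  yc <- y - mean(y)
  vg <- colSums(gc^2) / (n - 1)
  b <- as.vector(crossprod(gc, yc)) / ((n - 1) * vg)
  ssr <- sum(yc^2) - b^2 * (n - 1) * vg
  se <- sqrt(pmax(ssr, 0) / (n - 2) / ((n - 1) * vg))
  p <- 2 * stats::pnorm(-abs(b / se))
  list(beta = b, se = se, p = p, freq = gm / 2)
}

# Per-variant marginal logistic regression (log-odds effects) or the
# linear-probability shortcut rescaled by 1/(K(1-K)).
marginal_logistic <- function(g, y, method = c("logistic", "linear")) {
  method <- match.arg(method)
  if (method == "linear") {
    k <- mean(y)
    fit <- marginal_lm(g, y)
    return(list(beta = fit$beta / (k * (1 - k)), se = fit$se / (k * (1 - k)),
                p = fit$p, freq = fit$freq))
  }
  m <- ncol(g)
  beta <- se <- numeric(m)
  for (j in seq_len(m)) {
    fit <- stats::glm.fit(cbind(1, g[, j]), y, family = stats::binomial())
    w <- fit$weights
    x <- cbind(1, g[, j])
    vcov <- chol2inv(chol(crossprod(x * sqrt(w))))
    beta[j] <- fit$coefficients[2L]
    se[j] <- sqrt(vcov[2L, 2L])
  }
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)),
       freq = colMeans(g) / 2)
}

sim_dataset <- function(cfg, beta, se, p, freq, n, trait_id, trait_type,
                        ancestry = "EAS") {
  summary_dataset(data.frame(
    chrom = cfg$chrom, pos = sim_positions(cfg), rsid = sim_keys(cfg),
    effect_allele = "A", other_allele = "G",
    eaf = freq, beta = beta, se = se, pvalue = p, n = n,
    stringsAsFactors = FALSE),
    trait_id = trait_id, trait_type = trait_type, ancestry = ancestry)
}

# Joint standardized-genotype effect vector on the (unit-SD) exposure,
# plus the exposure SD implied by the config and target LD.
sim_exposure_effects <- function(cfg, r_target) {
  b_raw <- numeric(cfg$n_variants)
  b_raw[cfg$causal_idx] <- cfg$gamma
  vg <- drop(crossprod(b_raw, r_target %*% b_raw))
  sd_x <- sqrt(vg + cfg$exposure_noise_sd^2)
  list(b_std = b_raw / sd_x, sd_x = sd_x, vg = vg, h2 = vg / sd_x^2)
}

# Mediator construction on standardized scales: the mediator has unit
# variance by choosing its residual SD to absorb what the genetic and
# exposure paths do not explain.
sim_mediator_effects <- function(cfg, med, b_std_x, r_target) {
  d <- numeric(cfg$n_variants)
  d[med$own_idx] <- rep_len(med$own_effect, length(med$own_idx))
  cross <- drop(crossprod(b_std_x, r_target %*% d))
  var_gen <- med$alpha^2 + drop(crossprod(d, r_target %*% d)) + 2 * med$alpha * cross
  if (var_gen >= 1)
    stop("mediator spec explains more than unit variance", call. = FALSE)
  list(c_std = med$alpha * b_std_x + d, d = d,
       resid_sd = sqrt(1 - var_gen))
}

#' Simulate a two-sample (three-sample with mediators) GWAS study
#'
#' Produces exposure, mediator and outcome summary datasets over the
#' configured LD block, an LD matrix, and a `truth_manifest` recording
#' every ground-truth parameter for parameter-recovery tests.
#'
#' In `"individual"` mode, disjoint cohorts of genotypes are drawn, the
#' exposure `X = sum(gamma_j G_j) + eps` is scaled to unit SD, each
#' mediator follows its exposure path plus its own causal variants, the
#' outcome liability `theta * X + sum(beta_m M_m) + eps` (logistic
#' residual, so `theta_true` is a log-odds effect) is dichotomized
#' at the prevalence quantile, and marginal per-variant regressions
#' (linear, or logistic for the binary outcome) produce the summary
#' statistics; the LD matrix is estimated from the reference panel. In
#' `"summary"` mode the marginal estimates are drawn from their
#' asymptotic multivariate-normal distribution around the true marginal
#' effects (`R %*% b` for joint effects `b`), with the outcome on the
#' log-odds scale and effective precision `n * K * (1 - K)`; the LD
#' matrix is the target correlation.
#'
#' @param cfg a [sim_config()].
#' @param mode `"summary"` (fast, used for replicate studies) or
#'   `"individual"`.
#' @param binary_method marginal model for the binary outcome in
#'   individual mode: `"logistic"` or the `"linear"` probability
#'   shortcut rescaled to the log-odds scale.
#' @return list with elements `exposure`, `mediators` (named list),
#'   `outcome` (summary datasets), `ld` ([ld_matrix()]), and `truth`
#'   (a `truth_manifest` list).
#' @export
simulate_two_sample_study <- function(cfg, mode = c("summary", "individual"),
                                      binary_method = c("logistic", "linear")) {
  mode <- match.arg(mode)
  binary_method <- match.arg(binary_method)
  r_target <- sim_target_ld(cfg)
  mafs <- sim_mafs(cfg)
  keys <- sim_keys(cfg)
  s_allele <- sqrt(2 * mafs * (1 - mafs))
  ex <- sim_exposure_effects(cfg, r_target)
  meds <- lapply(cfg$mediators, sim_mediator_effects, cfg = cfg,
                 b_std_x = ex$b_std, r_target = r_target)
  alpha <- vapply(cfg$mediators, `[[`, 0, "alpha")
  beta_m <- vapply(cfg$mediators, `[[`, 0, "beta")
  theta_total <- cfg$theta_true + sum(alpha * beta_m)

  k <- cfg$prevalence
  if (mode == "summary") {
    ch <- chol(condition_psd(r_target, floor = 1e-8))
    draw <- function(b_joint, n, eff_n, stream) {
      mu <- drop(r_target %*% b_joint)
      set.seed(substream_seed(cfg$seed, stream))
      bh <- mu + drop(stats::rnorm(cfg$n_variants) %*% ch) / sqrt(eff_n)
      se <- rep(1 / sqrt(eff_n), cfg$n_variants)
      list(beta = bh / s_allele, se = se / s_allele,
           p = 2 * stats::pnorm(-abs(bh / se)), freq = mafs, n = n)
    }
    e <- draw(ex$b_std, cfg$n_exposure_cohort, cfg$n_exposure_cohort, "exposure")
    exposure <- sim_dataset(cfg, e$beta, e$se, e$p, e$freq,
                            cfg$n_exposure_cohort, "LDL", "quantitative")
    mediators <- list()
    for (nm in names(cfg$mediators)) {
      mm <- draw(meds[[nm]]$c_std, cfg$n_mediator_cohort,
                 cfg$n_mediator_cohort, paste0("mediator_", nm))
      mediators[[nm]] <- sim_dataset(cfg, mm$beta, mm$se, mm$p, mm$freq,
                                     cfg$n_mediator_cohort, nm, "quantitative")
    }
    u <- theta_total * ex$b_std
    for (nm in names(cfg$mediators)) u <- u + beta_m[[nm]] * meds[[nm]]$d
    # theta_total * b + beta * d: the (theta + alpha*beta) term runs
    # through the exposure's causal variants, the beta * d term through
    # each mediator's own variants.
    o <- draw(u, cfg$n_outcome_cohort,
              cfg$n_outcome_cohort * k * (1 - k), "outcome")
    outcome <- sim_dataset(cfg, o$beta, o$se, o$p, o$freq,
                           cfg$n_outcome_cohort, "T2D", "binary")
    ld <- ld_matrix(r_target, n_ref = cfg$n_ref_panel)
    exposure_sd <- ex$sd_x
  } else {
    g_ref <- simulate_genotypes(cfg, cfg$n_ref_panel, "ref")
    g_exp <- simulate_genotypes(cfg, cfg$n_exposure_cohort, "exposure")
    g_out <- simulate_genotypes(cfg, cfg$n_outcome_cohort, "outcome")
    stopifnot(length(intersect(rownames(g_exp), rownames(g_out))) == 0L)
    ld <- ld_from_genotypes(g_ref)

    std <- function(g) sweep(sweep(g, 2L, colMeans(g)), 2L,
                             apply(g, 2L, stats::sd), `/`)
    gamma_vec <- numeric(cfg$n_variants)
    gamma_vec[cfg$causal_idx] <- cfg$gamma
    set.seed(substream_seed(cfg$seed, "pheno_exposure"))
    x_raw <- drop(std(g_exp) %*% gamma_vec) +
      stats::rnorm(nrow(g_exp), 0, cfg$exposure_noise_sd)
    exposure_sd <- stats::sd(x_raw)
    fit <- marginal_lm(g_exp, x_raw / exposure_sd)
    exposure <- sim_dataset(cfg, fit$beta, fit$se, fit$p, fit$freq,
                            cfg$n_exposure_cohort, "LDL", "quantitative")

    mediators <- list()
    med_vals_out <- list()
    for (nm in names(cfg$mediators)) {
      gm <- simulate_genotypes(cfg, cfg$n_mediator_cohort, paste0("med_", nm))
      stopifnot(length(intersect(rownames(gm), rownames(g_out))) == 0L)
      set.seed(substream_seed(cfg$seed, paste0("pheno_med_", nm)))
      mval <- make_mediator(cfg, meds[[nm]], std(gm), nm)
      fitm <- marginal_lm(gm, mval)
      mediators[[nm]] <- sim_dataset(cfg, fitm$beta, fitm$se, fitm$p, fitm$freq,
                                     cfg$n_mediator_cohort, nm, "quantitative")
    }

    set.seed(substream_seed(cfg$seed, "pheno_outcome"))
    go_std <- std(g_out)
    x_out <- drop(go_std %*% gamma_vec) / exposure_sd +
      stats::rnorm(nrow(g_out), 0, cfg$exposure_noise_sd / exposure_sd)
    liab <- cfg$theta_true * x_out
    for (nm in names(cfg$mediators))
      liab <- liab + beta_m[[nm]] * make_mediator(cfg, meds[[nm]], go_std, nm)
    # logistic residual: thresholding this liability at the prevalence
    # quantile coincides with a logistic model for case status, so
    # theta_true is a log-odds-per-SD effect in both sampling modes
    liab <- liab + stats::rlogis(nrow(g_out))
    y <- as.integer(liab > stats::quantile(liab, 1 - k))
    fito <- marginal_logistic(g_out, y, method = binary_method)
    outcome <- sim_dataset(cfg, fito$beta, fito$se, fito$p, fito$freq,
                           cfg$n_outcome_cohort, "T2D", "binary")
  }

  truth <- structure(list(
    config = cfg, variant_keys = keys, mafs = mafs,
    positions = sim_positions(cfg),
    causal_keys = keys[cfg$causal_idx],
    exposure_sd = exposure_sd, h2_exposure = ex$h2,
    b_std_exposure = ex$b_std,
    marginal_std_exposure = drop(r_target %*% ex$b_std),
    theta_direct = cfg$theta_true, theta_total = theta_total,
    mediation_proportion = if (length(alpha))
      100 * (alpha * beta_m) / theta_total else numeric(0)),
    class = "truth_manifest")

  list(exposure = exposure, mediators = mediators, outcome = outcome,
       ld = ld, truth = truth)
}

# Mediator phenotype in a genotyped cohort: exposure path (through the
# cohort's own latent exposure value) plus the mediator's own variants.
make_mediator <- function(cfg, med_eff, g_std, nm) {
  n <- nrow(g_std)
  gamma_vec <- numeric(cfg$n_variants)
  gamma_vec[cfg$causal_idx] <- cfg$gamma
  ex <- sim_exposure_effects(cfg, sim_target_ld(cfg))
  x <- drop(g_std %*% gamma_vec) / ex$sd_x +
    stats::rnorm(n, 0, cfg$exposure_noise_sd / ex$sd_x)
  alpha <- cfg$mediators[[nm]]$alpha
  drop(alpha * x + g_std %*% med_eff$d + stats::rnorm(n, 0, med_eff$resid_sd))
}

#' Serialize a truth manifest to JSON
#' @param truth a `truth_manifest`.
#' @param path output file.
#' @export
write_truth_manifest <- function(truth, path) {
  x <- unclass(truth)
  x$config <- unclass(x$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a colocalization scenario over a region
#'
#' Generates two traits' regional summary statistics under a known
#' sharing hypothesis: `"shared"` puts one causal variant behind both
#' traits, `"distinct"` gives each trait its own causal variant with
#' r-squared below `distinct_r2_bound`, `"null"` leaves trait 2 with no
#' causal variant. Estimates are drawn in summary mode (asymptotic
#' normal around `R %*% b`).
#'
#' @param scenario `"shared"`, `"distinct"` or `"null"`.
#' @param cfg a [sim_config()] providing the block layout and seed.
#' @param n1,n2 GWAS sizes for the two traits.
#' @param q1,q2 variance in each trait explained by its causal variant.
#' @param causal_index causal variant for trait 1 (default: block
#'   center).
#' @param distinct_r2_bound LD ceiling between the two causal variants
#'   in the distinct scenario.
#' @return list with `trait1`, `trait2` (summary datasets), `ld`, and
#'   `truth` (scenario label and causal keys).
#' @export
simulate_coloc_scenario <- function(scenario = c("shared", "distinct", "null"),
                                    cfg = sim_config(), n1 = 20000L, n2 = 20000L,
                                    q1 = 0.01, q2 = 0.01,
                                    causal_index = NULL,
                                    distinct_r2_bound = 0.01) {
  scenario <- match.arg(scenario)
  r_target <- sim_target_ld(cfg)
  mafs <- sim_mafs(cfg)
  s_allele <- sqrt(2 * mafs * (1 - mafs))
  m <- cfg$n_variants
  j1 <- causal_index %||% ((m + 1L) %/% 2L)
  j2 <- NA_integer_
  b1 <- numeric(m); b1[j1] <- sqrt(q1)
  b2 <- numeric(m)
  if (scenario == "shared") {
    b2[j1] <- sqrt(q2); j2 <- j1
  } else if (scenario == "distinct") {
    ok <- which(r_target[j1, ]^2 < distinct_r2_bound)
    if (length(ok) == 0L)
      stop("no variant satisfies the distinct-causal r2 bound", call. = FALSE)
    j2 <- ok[which.max(abs(ok - j1))]
    b2[j2] <- sqrt(q2)
  }
  ch <- chol(condition_psd(r_target, floor = 1e-8))
  draw <- function(b, n, stream) {
    mu <- drop(r_target %*% b)
    set.seed(substream_seed(cfg$seed, stream))
    bh <- mu + drop(stats::rnorm(m) %*% ch) / sqrt(n)
    se <- rep(1 / sqrt(n), m)
    sim_dataset(cfg, bh / s_allele, se / s_allele,
                2 * stats::pnorm(-abs(bh / se)), mafs, n,
                trait_id = stream, trait_type = "quantitative")
  }
  list(trait1 = draw(b1, n1, "coloc_trait1"),
       trait2 = draw(b2, n2, "coloc_trait2"),
       ld = ld_matrix(r_target, n_ref = cfg$n_ref_panel),
       truth = list(scenario = scenario,
                    causal1 = sim_keys(cfg)[j1],
                    causal2 = if (is.na(j2)) NA_character_ else sim_keys(cfg)[j2]))
}
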