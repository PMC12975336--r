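# Replicate-study engines for calibration and parameter-recovery
# experiments. These loop the summary-mode generator (estimates drawn
# from their asymptotic distribution around the true marginal effects)
# through the package's own instrument selection and estimators, so
# ten-thousand-replicate calibrations run in seconds.

replicate_plan <- function(cfg) {
  r_target <- sim_target_ld(cfg)
  mafs <- sim_mafs(cfg)
  ex <- sim_exposure_effects(cfg, r_target)
  meds <- lapply(cfg$mediators, sim_mediator_effects, cfg = cfg,
                 b_std_x = ex$b_std, r_target = r_target)
  alpha <- vapply(cfg$mediators, `[[`, 0, "alpha")
  beta_m <- vapply(cfg$mediators, `[[`, 0, "beta")
  theta_total <- cfg$theta_true + sum(alpha * beta_m)
  u <- theta_total * ex$b_std
  for (i in seq_along(meds)) u <- u + beta_m[i] * meds[[i]]$d
  k <- cfg$prevalence
  list(cfg = cfg, r = r_target, mafs = mafs, keys = sim_keys(cfg),
       pos = sim_positions(cfg), chol = chol(condition_psd(r_target, 1e-8)),
       mu_x = drop(r_target %*% ex$b_std),
       mu_y = drop(r_target %*% u),
       mu_m = lapply(meds, function(m) drop(r_target %*% m$c_std)),
       med_own_idx = lapply(cfg$mediators, `[[`, "own_idx"),
       eff_nx = cfg$n_exposure_cohort,
       eff_ny = cfg$n_outcome_cohort * k * (1 - k),
       eff_nm = cfg$n_mediator_cohort,
       ld = ld_matrix(r_target, n_ref = cfg$n_ref_panel),
       theta_total = theta_total, alpha = alpha, beta_m = beta_m,
       region = gene_region_spec(cfg$gene_id, cfg$chrom, cfg$tss))
}

draw_std <- function(plan, mu, eff_n) {
  m <- length(mu)
  bh <- mu + drop(stats::rnorm(m) %*% plan$chol) / sqrt(eff_n)
  list(beta = bh, se = rep(1 / sqrt(eff_n), m),
       p = 2 * stats::pnorm(-abs(bh * sqrt(eff_n))))
}

plan_pairs <- function(plan, x, y) {
  structure(data.frame(chrom = plan$cfg$chrom, pos = plan$pos,
                       rsid = plan$keys, effect_allele = "A",
                       other_allele = "G", eaf_x = plan$mafs,
                       beta_x = x$beta, se_x = x$se, p_x = x$p,
                       n_x = plan$cfg$n_exposure_cohort,
                       eaf_y = plan$mafs, beta_y = y$beta, se_y = y$se,
                       p_y = y$p, n_y = plan$cfg$n_outcome_cohort,
                       stringsAsFactors = FALSE),
            outcome_type = "binary",
            class = c("harmonized_pairs", "data.frame"))
}

#' Replicate two-sample MR studies against known truth
#'
#' Repeatedly simulates a two-sample study in summary mode, selects
#' drug-target-region instruments with the standard filter tuple
#' (`p_max`, `r2_max` clumping), fits the correlated-instrument IVW
#' estimator, and records the estimate, its CI coverage of the true
#' total effect, the null-rejection indicator and Cochran's Q — the raw
#' material for type-I-error, bias and coverage checks.
#'
#' @param cfg a [sim_config()] defining the study conditions.
#' @param n_reps number of replicate studies.
#' @param seed replication master seed.
#' @param model IVW variance model (calibrations use `"fixed"`, the
#'   correct model under the generator's homogeneous effects).
#' @param p_max,r2_max instrument selection thresholds.
#' @param alpha nominal test level for the rejection indicator.
#' @return data.frame, one row per replicate: `theta`, `se`, `pvalue`,
#'   `n_snps`, `q_stat`, `q_pvalue`, `reject`, `covered`; the true
#'   effect is in attribute `"theta_total"`.
#' @export
replicate_mr_studies <- function(cfg, n_reps, seed = 1L, model = "fixed",
                                 p_max = 1e-8, r2_max = 0.3, alpha = 0.05) {
  plan <- replicate_plan(cfg)
  set.seed(substream_seed(seed, "mr_replicates"))
  out <- matrix(NA_real_, n_reps, 7L)
  for (r in seq_len(n_reps)) {
    x <- draw_std(plan, plan$mu_x, plan$eff_nx)
    y <- draw_std(plan, plan$mu_y, plan$eff_ny)
    keys <- clump(data.frame(chrom = plan$cfg$chrom, pos = plan$pos,
                             pvalue = x$p), plan$ld,
                  p_max = p_max, r2_max = r2_max)
    if (length(keys) == 0L) next
    inst <- instrument_set(plan_pairs(plan, x, y), plan$ld, keys = keys)
    est <- ivw_correlated(inst, model = model)
    out[r, ] <- c(est$theta, est$se, est$pvalue, est$n_snps,
                  est$q_stat %||% NA_real_, est$q_pvalue %||% NA_real_,
                  NA)
  }
  df <- as.data.frame(out[, 1:6, drop = FALSE])
  names(df) <- c("theta", "se", "pvalue", "n_snps", "q_stat", "q_pvalue")
  df$reject <- df$pvalue < alpha
  df$covered <- plan$theta_total >= df$theta - Z95 * df$se &
    plan$theta_total <= df$theta + Z95 * df$se
  attr(df, "theta_total") <- plan$theta_total
  df
}

#' Replicate mediation analyses against a planted mediation proportion
#'
#' Per replicate: the drug-target effect on the mediator (`alpha`) and
#' on the outcome (`total`) come from univariable correlated IVW on the
#' target-region instruments; the mediator's outcome effect adjusted
#' for the target (`beta`) comes from multivariable MR over the union
#' of target and mediator instruments; [mediation_product()] combines
#' them. The generator's planted proportion is
#' `100 * alpha * beta / theta_total`.
#'
#' @inheritParams replicate_mr_studies
#' @param mediator name of the mediator in `cfg$mediators`.
#' @return data.frame with `alpha`, `beta`, `total`, `indirect`,
#'   `proportion`; truth in attributes `"proportion_true"`.
#' @export
replicate_mediation_studies <- function(cfg, n_reps, seed = 1L,
                                        mediator = names(cfg$mediators)[1],
                                        p_max = 1e-8, r2_max = 0.3) {
  stopifnot(length(cfg$mediators) >= 1L)
  plan <- replicate_plan(cfg)
  mi <- match(mediator, names(cfg$mediators))
  set.seed(substream_seed(seed, "mediation_replicates"))
  out <- matrix(NA_real_, n_reps, 5L)
  for (r in seq_len(n_reps)) {
    x <- draw_std(plan, plan$mu_x, plan$eff_nx)
    y <- draw_std(plan, plan$mu_y, plan$eff_ny)
    mm <- draw_std(plan, plan$mu_m[[mi]], plan$eff_nm)
    keys_x <- clump(data.frame(chrom = plan$cfg$chrom, pos = plan$pos,
                               pvalue = x$p), plan$ld, p_max, r2_max)
    keys_m <- plan$keys[plan$med_own_idx[[mi]]]
    if (length(keys_x) == 0L) next
    # alpha: target region -> mediator
    inst_xm <- instrument_set(plan_pairs(plan, x, mm), plan$ld, keys = keys_x)
    fit_a <- ivw_correlated(inst_xm, model = "fixed")
    # total: target region -> outcome
    inst_xy <- instrument_set(plan_pairs(plan, x, y), plan$ld, keys = keys_x)
    fit_t <- ivw_correlated(inst_xy, model = "fixed")
    # beta: mediator -> outcome, adjusted for the target region (MVMR)
    keys_u <- union(keys_x, keys_m)
    pairs_u <- plan_pairs(plan, x, y)
    pairs_u$beta_m <- mm$beta; pairs_u$se_m <- mm$se
    inst_u <- instrument_set(pairs_u, plan$ld, keys = keys_u,
                             exposure_ids = "target")
    idx <- match(keys_u, plan$keys)
    inst_u$beta_x <- cbind(target = x$beta[idx], mediator = mm$beta[idx])
    inst_u$se_x <- cbind(target = x$se[idx], mediator = mm$se[idx])
    inst_u$exposure_ids <- c("target", "mediator")
    fit_b <- mvmr_correlated(inst_u, model = "fixed")[[2]]
    med <- mediation_product(fit_a$theta, fit_a$se, fit_b$theta, fit_b$se,
                             total = fit_t$theta, se_total = fit_t$se)
    out[r, ] <- c(fit_a$theta, fit_b$theta, fit_t$theta, med$indirect,
                  med$proportion_mediated)
  }
  df <- as.data.frame(out)
  names(df) <- c("alpha", "beta", "total", "indirect", "proportion")
  attr(df, "proportion_true") <-
    unname(100 * plan$alpha[mi] * plan$beta_m[mi] / plan$theta_total)
  df
}

#' Replicate colocalization scenarios
#'
#' Runs [simulate_coloc_scenario()] plus [coloc_abf()] `n_reps` times
#' under one sharing scenario and returns the posterior matrix.
#'
#' @param scenario `"shared"`, `"distinct"` or `"null"`.
#' @param cfg block configuration ([sim_config()]).
#' @param n_reps,seed replication controls.
#' @param ... passed to [simulate_coloc_scenario()] (`n1`, `q1`, ...).
#' @return matrix `n_reps x 5` of posteriors PP0..PP4.
#' @export
replicate_coloc_scenarios <- function(scenario, cfg = sim_config(),
                                      n_reps = 200L, seed = 1L, ...) {
  pp <- matrix(NA_real_, n_reps, 5L,
               dimnames = list(NULL, paste0("PP", 0:4)))
  for (r in seq_len(n_reps)) {
    cfg$seed <- substream_seed(seed, paste0("coloc_rep_", r))
    sim <- simulate_coloc_scenario(scenario, cfg = cfg, ...)
    res <- coloc_abf(sim$trait1, sim$trait2)
    pp[r, ] <- res$pp
  }
  pp
}

#' Replicate HEIDI tests under a single shared causal variant
#'
#' The null model of the HEIDI test: one causal variant drives both the
#' molecular trait and the outcome. Each replicate simulates the shared
#' scenario, assembles the regional instrument set, and runs
#' [heidi_test()]; the returned p-values support null-calibration
#' checks (rejection near the nominal level).
#'
#' @param cfg block configuration.
#' @param n_reps,seed replication controls.
#' @param n1,n2,q1,q2 scenario parameters (see
#'   [simulate_coloc_scenario()]).
#' @return data.frame with `p_heidi`, `n_used`, `p_smr`.
#' @export
replicate_heidi_null <- function(cfg = sim_config(), n_reps = 500L, seed = 1L,
                                 n1 = 20000L, n2 = 20000L, q1 = 0.02, q2 = 0.02) {
  out <- data.frame(p_heidi = rep(NA_real_, n_reps), n_used = NA_integer_,
                    p_smr = NA_real_)
  for (r in seq_len(n_reps)) {
    cfg$seed <- substream_seed(seed, paste0("heidi_rep_", r))
    sim <- simulate_coloc_scenario("shared", cfg = cfg, n1 = n1, n2 = n2,
                                   q1 = q1, q2 = q2)
    pairs <- harmonize(sim$trait1, sim$trait2)
    inst <- instrument_set(pairs, sim$ld)
    h <- heidi_test(inst)
    zx <- smr_zx(inst)
    top <- which.max(abs(zx))
    s <- smr_test(zx[top], smr_zy(inst)[top])
    out$p_heidi[r] <- h$p_heidi
    out$n_used[r] <- h$n_used
    out$p_smr[r] <- s$p_smr
  }
  out
}
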