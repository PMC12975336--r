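# Config-driven orchestration of the drug-target screen on simulated
# (or user-supplied) summary statistics: instrument selection per gene
# region, correlated IVW + Egger + Q per feature and ancestry,
# cross-ancestry fixed-effect meta-analysis, grouped FDR, mediation for
# nominated mediators, and colocalization + SMR/HEIDI over the region.

#' Screen configuration
#'
#' Collects the thresholds of the drug-target screen; defaults echo the
#' conventional drug-target MR tuple (instrument P < 1e-8, clumping
#' r-squared < 0.3, +/-1000 kb window, outcome-association removal at
#' P < 5e-8), colocalization priors `p1 = p2 = 1e-4`, `p12 = 1e-5`
#' with decision rules PP4 > 0.7 and HEIDI P > 0.05, and FDR < 0.05.
#'
#' @param sim a [sim_config()]; one study is simulated per ancestry
#'   label (seeds fanned out from `seed`).
#' @param ancestries ancestry labels for the per-population studies.
#' @param n_null_features number of extra null molecular features
#'   (no causal link to the target) screened alongside the mediators.
#' @param thresholds named list overriding any default threshold.
#' @param outdir output directory for the report tables.
#' @param seed master seed of the whole screen.
#' @return a `screen_config` list.
#' @export
screen_config <- function(sim = sim_config(),
                          ancestries = c("EAS", "EUR"),
                          n_null_features = 8L,
                          thresholds = list(),
                          outdir = tempfile("screen"),
                          seed = 1L) {
  th <- list(instrument_p = 1e-8, r2_max = 0.3, window_bp = 1e6,
             outcome_p = 5e-8, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
             pp4 = 0.7, heidi_p = 0.05, fdr = 0.05)
  th[names(thresholds)] <- thresholds
  structure(list(sim = sim, ancestries = ancestries,
                 n_null_features = as.integer(n_null_features),
                 thresholds = th, outdir = outdir, seed = as.integer(seed)),
            class = "screen_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the drug-target screen
#'
#' For each ancestry a study is simulated (summary mode) under the
#' configured conditions; target-region instruments are selected,
#' outcome-associated instruments removed, and every feature (the
#' configured mediators plus null features) is screened with correlated
#' IVW — plus MR-Egger and Cochran's Q where at least three instruments
#' remain. Per-feature results are meta-analysed across ancestries with
#' fixed effects and FDR-corrected within feature family; nominated
#' mediators get a mediation analysis, and the target region gets
#' colocalization and SMR/HEIDI against the outcome. A feature whose
#' analysis fails is recorded with its error and the run continues.
#'
#' Outputs under `config$outdir`: `mr_results.tsv`, `meta_results.tsv`,
#' `mediation.tsv`, `coloc_smr.tsv` and `manifest.json` (seed,
#' thresholds, package version — the closure needed to reproduce the
#' tables exactly).
#'
#' @param config a [screen_config()].
#' @return list of the output tables (invisibly also written to disk).
#' @export
run_drug_target_screen <- function(config) {
  th <- config$thresholds
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  region <- gene_region_spec(config$sim$gene_id, config$sim$chrom,
                             config$sim$tss, th$window_bp)

  mr_rows <- list(); med_rows <- list(); coloc_rows <- list()
  for (anc in config$ancestries) {
    cfg <- config$sim
    cfg$seed <- substream_seed(config$seed, paste0("study_", anc))
    study <- simulate_two_sample_study(cfg, mode = "summary")
    plan <- replicate_plan(cfg)

    # feature panel: planted mediators + pure-null molecular features
    features <- study$mediators
    fam <- rep("metabolite", length(features))
    for (i in seq_len(config$n_null_features)) {
      nm <- sprintf("null_feature_%02d", i)
      x <- study$exposure
      set.seed(substream_seed(cfg$seed, paste0("feature_", nm)))
      bh <- drop(stats::rnorm(cfg$n_variants) %*% plan$chol) /
        sqrt(cfg$n_mediator_cohort)
      se <- rep(1 / sqrt(cfg$n_mediator_cohort), cfg$n_variants)
      s_allele <- sqrt(2 * plan$mafs * (1 - plan$mafs))
      features[[nm]] <- sim_dataset(cfg, bh / s_allele, se / s_allele,
                                    2 * stats::pnorm(-abs(bh / se)),
                                    plan$mafs, cfg$n_mediator_cohort,
                                    nm, "quantitative", ancestry = anc)
      fam <- c(fam, "protein")
    }

    for (fi in seq_along(features)) {
      nm <- names(features)[fi]
      row <- tryCatch({
        pairs <- harmonize(study$exposure, features[[fi]])
        inst <- select_gene_region_instruments(pairs, region, study$ld,
                                               p_max = th$instrument_p,
                                               r2_max = th$r2_max)
        inst <- drop_outcome_associated(inst, th$outcome_p)
        est <- ivw_correlated(inst)
        egger <- if (n_instruments(inst) >= 3L)
          mr_egger_correlated(inst) else NULL
        data.frame(ancestry = anc, feature = nm, family = fam[fi],
                   n_snps = est$n_snps, theta = est$theta, se = est$se,
                   ci_low = est$ci_low, ci_high = est$ci_high,
                   pvalue = est$pvalue, q_stat = est$q_stat,
                   q_pvalue = est$q_pvalue,
                   egger_intercept = if (is.null(egger)) NA_real_ else egger$egger_intercept,
                   egger_intercept_se = if (is.null(egger)) NA_real_ else egger$intercept_se,
                   error = "", stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(ancestry = anc, feature = nm, family = fam[fi],
                   n_snps = NA_integer_, theta = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_,
                   q_stat = NA_real_, q_pvalue = NA_real_,
                   egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                   error = conditionMessage(e), stringsAsFactors = FALSE))
      mr_rows[[paste(anc, nm)]] <- row
    }

    # target -> outcome within this ancestry: mediation + coloc + SMR
    pairs_y <- harmonize(study$exposure, study$outcome)
    inst_y <- select_gene_region_instruments(pairs_y, region, study$ld,
                                             p_max = th$instrument_p,
                                             r2_max = th$r2_max)
    total <- ivw_correlated(inst_y)
    for (nm in names(study$mediators)) {
      mrow <- tryCatch({
        rme <- mr_rows[[paste(anc, nm)]]
        if (nzchar(rme$error)) stop("feature-level MR failed: ", rme$error)
        mspec <- cfg$mediators[[nm]]
        # beta: mediator -> outcome adjusted for the target (MVMR over
        # the union of target and mediator-own instruments); all effect
        # columns stay on the per-allele scale, which is row-consistent
        # with the outcome side.
        keys_u <- union(inst_y$variants,
                        sim_keys(cfg)[mspec$own_idx])
        im <- instrument_set(pairs_y, study$ld, keys = keys_u)
        mfit <- as.data.frame(study$mediators[[nm]])
        idx <- match(keys_u, position_key(mfit$chrom, mfit$pos))
        im$beta_x <- cbind(target = im$beta_x[, 1], mediator = mfit$beta[idx])
        im$se_x <- cbind(target = im$se_x[, 1], mediator = mfit$se[idx])
        im$exposure_ids <- c("target", "mediator")
        bfit <- mvmr_correlated(im)[[2]]
        med <- mediation_product(rme$theta, rme$se, bfit$theta, bfit$se,
                                 total = total$theta, se_total = total$se)
        data.frame(ancestry = anc, mediator = nm, alpha = med$alpha,
                   se_alpha = med$se_alpha, beta = med$beta,
                   se_beta = med$se_beta, indirect = med$indirect,
                   se_indirect = med$se_indirect, total = med$total,
                   proportion_mediated = med$proportion_mediated,
                   se_fallback = med$se_fallback, error = "",
                   stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(ancestry = anc, mediator = nm, alpha = NA_real_,
                   se_alpha = NA_real_, beta = NA_real_, se_beta = NA_real_,
                   indirect = NA_real_, se_indirect = NA_real_,
                   total = NA_real_, proportion_mediated = NA_real_,
                   se_fallback = NA, error = conditionMessage(e),
                   stringsAsFactors = FALSE))
      med_rows[[paste(anc, nm)]] <- mrow
    }

    coloc_rows[[anc]] <- tryCatch({
      cres <- coloc_abf(pairs_y, region = region,
                        p1 = th$p1, p2 = th$p2, p12 = th$p12)
      inst_all <- instrument_set(pairs_y, study$ld)
      zx <- smr_zx(inst_all); zy <- smr_zy(inst_all)
      top <- which.max(abs(zx))
      s1 <- smr_test(zx[top], zy[top],
                     inst_all$beta_x[top, 1], inst_all$beta_y[top])
      sm <- smr_multi(inst_all, p_qtl_threshold = th$outcome_p)
      hd <- heidi_test(inst_all)
      data.frame(ancestry = anc, region = region$gene_id,
                 top_variant = inst_all$variants[top],
                 b_smr = s1$b_smr, se_smr = s1$se_smr, p_smr = s1$p_smr,
                 p_smr_multi = sm$p_smr_multi, p_heidi = hd$p_heidi,
                 n_heidi_snps = hd$n_used, pp4 = unname(cres$pp["PP4"]),
                 coloc_class = classify_coloc(cres, th$pp4),
                 prioritized = cres$pp["PP4"] > th$pp4 &
                   !is.na(hd$p_heidi) & hd$p_heidi > th$heidi_p &
                   s1$p_smr < 0.05,
                 error = "", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(ancestry = anc, region = region$gene_id,
                 top_variant = NA_character_, b_smr = NA_real_,
                 se_smr = NA_real_, p_smr = NA_real_, p_smr_multi = NA_real_,
                 p_heidi = NA_real_, n_heidi_snps = NA_integer_,
                 pp4 = NA_real_, coloc_class = NA_character_,
                 prioritized = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
  }

  mr_tab <- do.call(rbind, mr_rows)
  rownames(mr_tab) <- NULL

  # cross-ancestry fixed-effect meta per feature, FDR within family
  meta_rows <- list()
  for (nm in unique(mr_tab$feature)) {
    sub <- mr_tab[mr_tab$feature == nm & is.finite(mr_tab$theta), ]
    if (nrow(sub) == 0L) next
    mres <- fixed_effect_meta(sub$theta, sub$se)
    meta_rows[[nm]] <- data.frame(
      feature = nm, family = sub$family[1], k = mres$k,
      theta_meta = mres$theta_meta, se_meta = mres$se_meta,
      ci_low = mres$ci_low, ci_high = mres$ci_high,
      pvalue = mres$pvalue, i2 = mres$i2, stringsAsFactors = FALSE)
  }
  meta_tab <- do.call(rbind, meta_rows)
  rownames(meta_tab) <- NULL
  meta_tab$qvalue <- bh_fdr(meta_tab$pvalue, meta_tab$family)
  meta_tab$fdr_significant <- meta_tab$qvalue < th$fdr

  med_tab <- if (length(med_rows)) do.call(rbind, med_rows) else
    data.frame()
  rownames(med_tab) <- NULL
  coloc_tab <- do.call(rbind, coloc_rows)
  rownames(coloc_tab) <- NULL

  write_tsv(mr_tab, file.path(config$outdir, "mr_results.tsv"))
  write_tsv(meta_tab, file.path(config$outdir, "meta_results.tsv"))
  if (nrow(med_tab)) write_tsv(med_tab, file.path(config$outdir, "mediation.tsv"))
  write_tsv(coloc_tab, file.path(config$outdir, "coloc_smr.tsv"))
  manifest <- list(package = "statinmr",
                   version = as.character(utils::packageVersion("statinmr")),
                   seed = config$seed, ancestries = config$ancestries,
                   thresholds = th,
                   sim = unclass(config$sim),
                   n_null_features = config$n_null_features)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(mr = mr_tab, meta = meta_tab, mediation = med_tab,
                 coloc_smr = coloc_tab, manifest = manifest,
                 outdir = config$outdir))
}
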