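# LD estimation from a reference panel, greedy clumping, and
# drug-target gene-region instrument selection.

#' Construct an LD correlation matrix object
#'
#' @param r square matrix of dosage correlations with variant keys as
#'   dimnames.
#' @param n_ref number of reference-panel samples the correlations were
#'   estimated from.
#' @param condition if `TRUE` (default) the matrix is conditioned to
#'   positive semi-definiteness (see [condition_psd()]).
#' @return an `ld_matrix`.
#' @export
ld_matrix <- function(r, n_ref = NA_integer_, condition = TRUE) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(rownames(r))) stop("LD matrix needs variant keys as dimnames", call. = FALSE)
  if (max(abs(r - t(r))) > 1e-6) stop("LD matrix is not symmetric", call. = FALSE)
  if (max(abs(diag(r) - 1)) > 1e-6) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (max(abs(r)) > 1 + 1e-6) stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  if (condition) r <- condition_psd(r)
  diag(r) <- 1
  structure(r, n_ref = n_ref, class = c("ld_matrix", "matrix"))
}

#' Estimate LD from reference-panel genotypes
#'
#' Pearson correlation of mean-centered allele dosages (0/1/2 integers
#' or continuous in `[0, 2]`). Monomorphic variants are dropped with a
#' message. The estimate is PSD-conditioned before return, since
#' correlation matrices subset from small panels are often indefinite.
#'
#' @param genotypes numeric matrix, samples in rows, variants in
#'   columns, variant keys as column names.
#' @return an `ld_matrix` over the polymorphic variants.
#' @export
ld_from_genotypes <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2L) stop("need at least 2 reference samples", call. = FALSE)
  v <- apply(genotypes, 2L, stats::var)
  mono <- v <= 0 | !is.finite(v)
  if (all(mono)) stop("degenerate panel: all variants monomorphic", call. = FALSE)
  if (any(mono))
    message("dropping ", sum(mono), " monomorphic variant(s) from the LD panel")
  ld_matrix(stats::cor(genotypes[, !mono, drop = FALSE]), n_ref = nrow(genotypes))
}

#' Greedy LD clumping
#'
#' Standard p-value-ranked clumping: variants with `pvalue < p_max`
#' enter; the best remaining variant is kept and every remaining variant
#' with squared correlation `>= r2_max` against it is discarded, until
#' none remain. Ties on p-value are broken by chrom:pos order so the
#' result does not depend on input row order.
#'
#' @param records data.frame with columns `chrom`, `pos`, `pvalue` (a
#'   `summary_dataset` works).
#' @param ld an [ld_matrix()] covering every record.
#' @param p_max inclusion p-value threshold.
#' @param r2_max pairwise r-squared ceiling between retained variants.
#' @return character vector of retained variant position keys
#'   (`chrom:pos`), ordered by ascending p-value.
#' @export
clump <- function(records, ld, p_max = 1e-8, r2_max = 0.3) {
  df <- as.data.frame(records)
  df$key <- position_key(df$chrom, df$pos)
  missing <- setdiff(df$key, rownames(ld))
  if (length(missing))
    stop("variant(s) absent from the LD matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  df <- df[df$pvalue < p_max, , drop = FALSE]
  if (nrow(df) == 0L) return(character(0))
  ord <- order(df$pvalue, df$chrom, df$pos)
  df <- df[ord, ]
  keep <- character(0)
  remaining <- df$key
  while (length(remaining)) {
    top <- remaining[1]
    keep <- c(keep, top)
    r2 <- ld[top, remaining]^2
    remaining <- remaining[r2 < r2_max & remaining != top]
  }
  keep
}

#' Gene region specification
#'
#' A cis window around a gene's transcription start site, the unit over
#' which drug-target instruments, colocalization and SMR analyses
#' operate. Built-in TSS coordinates (GRCh37) are provided for the
#' lipid-drug target genes; pass explicit coordinates for anything else.
#'
#' @param gene_id gene symbol.
#' @param chrom,tss chromosome and 1-based TSS position; looked up in
#'   the built-in table when omitted.
#' @param window_bp half-width of the cis window (default 1e6, i.e.
#'   +/-1000 kb around the TSS).
#' @return a `gene_region_spec` list.
#' @export
gene_region_spec <- function(gene_id, chrom = NULL, tss = NULL, window_bp = 1e6) {
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  if (is.null(chrom) || is.null(tss)) {
    hit <- drug_target_genes[drug_target_genes$gene_id == gene_id, ]
    if (nrow(hit) != 1L)
      stop("no built-in coordinates for gene '", gene_id,
           "'; supply chrom and tss", call. = FALSE)
    chrom <- hit$chrom; tss <- hit$tss
  }
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 tss = as.numeric(tss), window_bp = as.numeric(window_bp)),
            class = "gene_region_spec")
}

# Approximate GRCh37 TSS coordinates for the drug-target genes analysed
# in lipid-lowering pharmacogenetics; overridable via gene_region_spec().
drug_target_genes <- data.frame(
  gene_id = c("HMGCR", "LDLR", "PCSK9", "GIP"),
  chrom = c("5", "19", "1", "17"),
  tss = c(74632154, 11200038, 55505221, 46974671),
  stringsAsFactors = FALSE
)

#' Assemble an instrument set
#'
#' Packages harmonized exposure/outcome effects for a chosen variant
#' list together with the matching LD submatrix; the unit every MR
#' estimator consumes. `beta_x`/`se_x` may have several columns for
#' multivariable MR.
#'
#' @param pairs a `harmonized_pairs` table (see [harmonize()]), or any
#'   data.frame with the same columns.
#' @param ld an [ld_matrix()] covering the variants.
#' @param keys position keys to retain, in order; defaults to all rows.
#' @param exposure_ids,outcome_id trait labels carried through to
#'   results.
#' @return an `instrument_set`.
#' @export
instrument_set <- function(pairs, ld, keys = NULL,
                           exposure_ids = attr(pairs, "exposure_id") %||% "exposure",
                           outcome_id = attr(pairs, "outcome_id") %||% "outcome") {
  df <- as.data.frame(pairs)
  df$key <- position_key(df$chrom, df$pos)
  if (is.null(keys)) keys <- df$key
  idx <- match(keys, df$key)
  if (anyNA(idx)) stop("instrument keys missing from the pair table", call. = FALSE)
  df <- df[idx, , drop = FALSE]
  if (!all(keys %in% rownames(ld)))
    stop("instrument keys missing from the LD matrix", call. = FALSE)
  sub <- condition_psd(unclass(ld)[keys, keys, drop = FALSE])
  bx <- as.matrix(df$beta_x); sx <- as.matrix(df$se_x)
  colnames(bx) <- colnames(sx) <- exposure_ids
  structure(list(variants = keys,
                 beta_x = bx, se_x = sx,
                 beta_y = df$beta_y, se_y = df$se_y,
                 p_x = df$p_x, p_y = df$p_y,
                 ld = sub, n_ref = attr(ld, "n_ref"),
                 exposure_ids = exposure_ids, outcome_id = outcome_id,
                 outcome_type = attr(pairs, "outcome_type") %||% "quantitative"),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("InstrumentSet: %d variant(s), exposure(s) %s -> outcome %s\n",
              length(x$variants), paste(x$exposure_ids, collapse = "+"),
              x$outcome_id))
  invisible(x)
}

n_instruments <- function(inst) length(inst$variants)

subset_instruments <- function(inst, keep) {
  if (is.logical(keep)) keep <- which(keep)
  inst$variants <- inst$variants[keep]
  inst$beta_x <- inst$beta_x[keep, , drop = FALSE]
  inst$se_x <- inst$se_x[keep, , drop = FALSE]
  inst$beta_y <- inst$beta_y[keep]
  inst$se_y <- inst$se_y[keep]
  inst$p_x <- inst$p_x[keep]
  inst$p_y <- inst$p_y[keep]
  inst$ld <- condition_psd(inst$ld[keep, keep, drop = FALSE])
  inst
}

#' Select drug-target instruments in a gene region
#'
#' Applies the drug-target instrument filter: restrict the exposure scan
#' to `tss +/- window_bp`, keep variants below the significance
#' threshold, and clump to an approximately independent set
#' (`r^2 < r2_max`). Defaults reproduce the conventional drug-target MR
#' tuple (+/-1000 kb, P < 1e-8, r^2 < 0.3).
#'
#' @param pairs harmonized exposure/outcome pairs ([harmonize()]).
#' @param region a [gene_region_spec()].
#' @param ld an [ld_matrix()].
#' @param p_max exposure p-value threshold (default 1e-8).
#' @param r2_max clumping r-squared ceiling (default 0.3).
#' @return an `instrument_set` restricted to the selected variants.
#' @export
select_gene_region_instruments <- function(pairs, region, ld,
                                           p_max = 1e-8, r2_max = 0.3) {
  df <- as.data.frame(pairs)
  in_region <- df$chrom == region$chrom &
    abs(df$pos - region$tss) <= region$window_bp
  df <- df[in_region, , drop = FALSE]
  keys <- character(0)
  if (nrow(df)) {
    sub <- data.frame(chrom = df$chrom, pos = df$pos, pvalue = df$p_x)
    keys <- clump(sub, ld, p_max = p_max, r2_max = r2_max)
  }
  if (length(keys) == 0L)
    stop("no instrument passes the filters in region ", region$gene_id,
         call. = FALSE)
  instrument_set(pairs, ld, keys = keys)
}

#' Rescale instruments per one standard deviation decrease in exposure
#'
#' Divides the exposure effects by the exposure's phenotypic SD and
#' flips their signs, so downstream causal estimates are expressed per
#' 1-SD *decrease* in the exposure — the convention for genetically
#' proxied lipid-lowering therapy, where the instrument mimics the
#' drug's LDL-C-lowering action. Outcome effects are untouched.
#'
#' @param instruments an `instrument_set`.
#' @param exposure_sd positive phenotypic SD of the exposure.
#' @return the rescaled `instrument_set`.
#' @export
scale_to_sd_decrease <- function(instruments, exposure_sd) {
  if (!is.numeric(exposure_sd) || exposure_sd <= 0)
    stop("exposure_sd must be positive", call. = FALSE)
  instruments$beta_x <- -instruments$beta_x / exposure_sd
  instruments$se_x <- instruments$se_x / exposure_sd
  instruments
}

#' Drop instruments directly associated with the outcome
#'
#' Removes variants whose outcome association is genome-wide significant
#' (default P < 5e-8), guarding the exclusion-restriction assumption
#' that instruments act on the outcome only through the exposure.
#' Outcome p-values are recomputed from `|beta_y/se_y|` when absent.
#'
#' @param instruments an `instrument_set`.
#' @param outcome_p_threshold removal threshold (default 5e-8).
#' @return the filtered `instrument_set`; attribute `"removed"` lists
#'   dropped variant keys.
#' @export
drop_outcome_associated <- function(instruments, outcome_p_threshold = 5e-8) {
  if (n_instruments(instruments) == 0L)
    stop("empty instrument set", call. = FALSE)
  p <- instruments$p_y
  miss <- !is.finite(p)
  p[miss] <- 2 * stats::pnorm(-abs(instruments$beta_y[miss] / instruments$se_y[miss]))
  drop <- p < outcome_p_threshold
  if (all(drop))
    stop("all instruments are directly associated with the outcome at P < ",
         format(outcome_p_threshold), call. = FALSE)
  removed <- instruments$variants[drop]
  out <- subset_instruments(instruments, !drop)
  attr(out, "removed") <- removed
  out
}

#' Export/import LD matrices as plain text
#'
#' Square tab-delimited correlation values with the variant keys as a
#' header line, readable back with [read_ld()].
#'
#' @param ld an [ld_matrix()].
#' @param path output file.
#' @export
write_ld <- function(ld, path) {
  utils::write.table(format(unclass(ld), digits = 7), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ld
#' @param n_ref reference sample count to attach on import.
#' @export
read_ld <- function(path, n_ref = NA_integer_) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  rownames(m) <- colnames(m)
  ld_matrix(m, n_ref = n_ref)
}
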