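# GWAS summary-statistic containers, readers/writers, and cross-dataset
# allele harmonization. A SummaryDataset is a data.frame with one row
# per variant and trait metadata in attributes; every downstream module
# consumes either this container or the harmonized pair table.

SUMSTATS_COLS <- c("chrom", "pos", "rsid", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

#' Construct a summary dataset
#'
#' Validates and packages per-variant marginal association records for a
#' single trait: effect sizes (`beta`, linear units for quantitative
#' traits, log-odds for binary traits), standard errors, p-values,
#' alleles and effect-allele frequencies.
#'
#' Rows with non-positive standard errors, malformed alleles, or
#' frequencies outside `[0, 1]` are dropped and counted in the load
#' report (attribute `"load_report"`). Variants sharing a position with
#' a different allele pair (multi-allelic sites) are dropped entirely.
#' Missing p-values are recomputed from `|beta/se|` under the normal
#' approximation; p-values disagreeing with that approximation by more
#' than two orders of magnitude trigger a warning but are kept.
#'
#' @param df data.frame with columns `chrom`, `pos`, `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @param trait_id short trait label.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param ancestry ancestry label, e.g. `"EAS"`, `"EUR"`.
#' @return a `summary_dataset` (a data.frame subclass).
#' @export
summary_dataset <- function(df, trait_id, trait_type = c("quantitative", "binary"),
                            ancestry = "other") {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing_cols))
    stop("summary dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[SUMSTATS_COLS]
  rows_in <- nrow(df)

  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  rejected <- list()

  ok_allele <- grepl("^[ACGT]+$", df$effect_allele) &
    grepl("^[ACGT]+$", df$other_allele) &
    df$effect_allele != df$other_allele
  rejected$bad_alleles <- sum(!ok_allele)
  df <- df[ok_allele, , drop = FALSE]

  ok_se <- is.finite(df$se) & df$se > 0
  rejected$nonpositive_se <- sum(!ok_se)
  df <- df[ok_se, , drop = FALSE]

  ok_eaf <- is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)
  rejected$bad_eaf <- sum(!ok_eaf)
  df <- df[ok_eaf, , drop = FALSE]

  # multi-allelic sites: same position, more than one allele pair
  pk <- position_key(df$chrom, df$pos)
  ak <- variant_key(df$chrom, df$pos, df$effect_allele, df$other_allele)
  n_pairs <- tapply(ak, pk, function(k) length(unique(k)))
  multi <- unname(n_pairs[pk] > 1)
  if (length(multi) == 0L) multi <- logical(0)
  rejected$multiallelic <- sum(multi)
  df <- df[!multi, , drop = FALSE]

  dup <- duplicated(variant_key(df$chrom, df$pos, df$effect_allele, df$other_allele))
  rejected$duplicate <- sum(dup)
  df <- df[!dup, , drop = FALSE]

  z <- abs(df$beta / df$se)
  p_norm <- 2 * stats::pnorm(-z)
  fill <- !is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  df$pvalue[fill] <- p_norm[fill]
  disagree <- !fill & p_norm > 0 & abs(log10(df$pvalue) - log10(p_norm)) > 2
  if (any(disagree))
    warning(sum(disagree), " p-value(s) disagree with |beta/se| by more than ",
            "two orders of magnitude in trait '", trait_id, "'", call. = FALSE)

  rownames(df) <- NULL
  structure(df,
            trait_id = trait_id, trait_type = trait_type, ancestry = ancestry,
            load_report = list(rows_in = rows_in, rows_kept = nrow(df),
                               rows_rejected = rows_in - nrow(df),
                               reasons = rejected),
            class = c("summary_dataset", "data.frame"))
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("SummaryDataset '%s' (%s, %s): %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"),
              attr(x, "ancestry"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Load report of a summary dataset
#' @param dataset a `summary_dataset`.
#' @return list with `rows_in`, `rows_kept`, `rows_rejected` and
#'   per-reason rejection counts.
#' @export
load_report <- function(dataset) attr(dataset, "load_report")

parse_chr_pos <- function(id) {
  m <- regmatches(id, regexec("^(chr)?([0-9XYMT]+):([0-9]+)", id))
  chrom <- vapply(m, function(g) if (length(g)) g[3] else NA_character_, "")
  pos <- vapply(m, function(g) if (length(g)) as.numeric(g[4]) else NA_real_, 0)
  list(chrom = chrom, pos = pos)
}

#' Read GWAS summary statistics
#'
#' Two dialects are supported. `cojo_ma` is the whitespace-delimited
#' COJO `.ma` layout with header `SNP A1 A2 freq b se p N` (`A1` is the
#' effect allele); variant positions are recovered from identifiers of
#' the form `chr:pos` (optionally suffixed with alleles). `generic_tsv`
#' is a tab-delimited file read through a user column map naming, at
#' minimum, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#' `se`.
#'
#' @param path input file.
#' @param dialect `"cojo_ma"` or `"generic_tsv"`.
#' @param trait_id,trait_type,ancestry trait metadata (see
#'   [summary_dataset()]).
#' @param col_map named character vector mapping canonical column names
#'   to file column names (generic_tsv only).
#' @return a `summary_dataset`; its `"load_report"` attribute counts
#'   dropped rows.
#' @export
read_sumstats <- function(path, dialect = c("cojo_ma", "generic_tsv"),
                          trait_id = basename(path),
                          trait_type = "quantitative", ancestry = "other",
                          col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e)
      stop("empty or malformed summary-statistics file: ", path, call. = FALSE))
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path, call. = FALSE)

  if (dialect == "cojo_ma") {
    req <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
    miss <- setdiff(req, names(raw))
    if (length(miss))
      stop("cojo_ma file lacks required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    cp <- parse_chr_pos(as.character(raw$SNP))
    df <- data.frame(chrom = cp$chrom, pos = cp$pos, rsid = as.character(raw$SNP),
                     effect_allele = raw$A1, other_allele = raw$A2,
                     eaf = as.numeric(raw$freq), beta = as.numeric(raw$b),
                     se = as.numeric(raw$se), pvalue = as.numeric(raw$p),
                     n = as.numeric(raw$N), stringsAsFactors = FALSE)
  } else {
    default_map <- c(chrom = "chrom", pos = "pos", rsid = "rsid",
                     effect_allele = "effect_allele", other_allele = "other_allele",
                     eaf = "eaf", beta = "beta", se = "se", pvalue = "pvalue", n = "n")
    map <- default_map
    if (!is.null(col_map)) map[names(col_map)] <- col_map
    req <- c("chrom", "pos", "effect_allele", "other_allele", "beta", "se")
    miss <- req[!map[req] %in% names(raw)]
    if (length(miss))
      stop("generic_tsv file lacks required column(s): ",
           paste(map[miss], collapse = ", "), call. = FALSE)
    get <- function(canon, default = NA) {
      if (map[[canon]] %in% names(raw)) raw[[map[[canon]]]] else rep(default, nrow(raw))
    }
    df <- data.frame(chrom = as.character(get("chrom")), pos = as.numeric(get("pos")),
                     rsid = as.character(get("rsid", NA_character_)),
                     effect_allele = get("effect_allele"), other_allele = get("other_allele"),
                     eaf = as.numeric(get("eaf")), beta = as.numeric(get("beta")),
                     se = as.numeric(get("se")), pvalue = as.numeric(get("pvalue")),
                     n = as.numeric(get("n")), stringsAsFactors = FALSE)
  }
  # unparseable positions cannot be matched positionally; drop and count
  bad_pos <- !is.finite(df$pos)
  n_bad_pos <- sum(bad_pos)
  df <- df[!bad_pos, , drop = FALSE]
  ds <- summary_dataset(df, trait_id = trait_id, trait_type = trait_type,
                        ancestry = ancestry)
  rep <- attr(ds, "load_report")
  rep$rows_in <- rep$rows_in + n_bad_pos
  rep$rows_rejected <- rep$rows_rejected + n_bad_pos
  rep$reasons$unparseable_position <- n_bad_pos
  attr(ds, "load_report") <- rep
  ds
}

#' Write GWAS summary statistics
#'
#' Writes in a deterministic column order with at least eight
#' significant digits, so that a write/read round trip reproduces the
#' records to well within 1e-6 relative error.
#'
#' @param dataset a `summary_dataset`.
#' @param path output file.
#' @param dialect output dialect (see [read_sumstats()]).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dataset, path, dialect = c("cojo_ma", "generic_tsv")) {
  dialect <- match.arg(dialect)
  if (nrow(dataset) == 0L) stop("refusing to write an empty dataset", call. = FALSE)
  df <- as.data.frame(dataset)
  if (dialect == "cojo_ma") {
    snp <- ifelse(is.na(df$rsid) | df$rsid == "",
                  position_key(df$chrom, df$pos), df$rsid)
    out <- data.frame(SNP = snp, A1 = df$effect_allele, A2 = df$other_allele,
                      freq = fmt_num(df$eaf), b = fmt_num(df$beta),
                      se = fmt_num(df$se), p = fmt_num(df$pvalue),
                      N = fmt_num(df$n))
  } else {
    out <- df
    for (col in c("eaf", "beta", "se", "pvalue", "n")) out[[col]] <- fmt_num(df[[col]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write summary statistics to ", path, call. = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) {
  vapply(strsplit(a, ""), function(ch) paste(rev(COMPLEMENT[ch]), collapse = ""), "")
}

is_palindromic <- function(a1, a2) {
  nchar(a1) == 1L & nchar(a2) == 1L & complement_allele(a1) == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants positionally (chrom:pos) and aligns the outcome's
#' effect allele to the exposure's. When the outcome reports its effect
#' for the exposure's other allele, the outcome beta sign is flipped and
#' its frequency complemented; strand-flipped (complemented) codings are
#' resolved the same way. Palindromic variants (A/T, C/G) carry no
#' strand information in their alleles, so they are handled by
#' `palindrome_policy`: `"drop"` removes them, `"freq_infer"` orients
#' them by allele frequency but drops any variant whose minor-allele
#' frequency exceeds `maf_ambiguity_bound` (or whose frequency is
#' missing) as ambiguous. Variants whose allele pairs cannot be
#' reconciled at all are dropped and logged.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param palindrome_policy `"freq_infer"` (default) or `"drop"`.
#' @param maf_ambiguity_bound MAF above which a palindromic variant's
#'   orientation is deemed ambiguous (default 0.42).
#' @return a `harmonized_pairs` data.frame with columns
#'   `chrom, pos, rsid, effect_allele, other_allele, eaf_x, beta_x,
#'   se_x, p_x, n_x, eaf_y, beta_y, se_y, p_y, n_y`; the
#'   `"harmonization_log"` attribute counts drops by reason.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("freq_infer", "drop"),
                      maf_ambiguity_bound = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  ex <- as.data.frame(exposure)
  oy <- as.data.frame(outcome)
  ex$key <- position_key(ex$chrom, ex$pos)
  oy$key <- position_key(oy$chrom, oy$pos)
  shared <- intersect(ex$key, oy$key)
  if (length(shared) == 0L)
    stop("no overlapping variants between exposure and outcome", call. = FALSE)
  ex <- ex[match(shared, ex$key), ]
  oy <- oy[match(shared, oy$key), ]

  log <- c(palindromic_dropped = 0L, palindromic_ambiguous = 0L,
           irreconcilable_alleles = 0L)
  keep <- logical(length(shared))
  beta_y <- oy$beta
  eaf_y <- oy$eaf

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  for (i in seq_along(shared)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    ya <- oy$effect_allele[i]; yb <- oy$other_allele[i]
    if (pal[i]) {
      # outcome alleles must be the same pair (possibly swapped)
      if (!setequal(c(ya, yb), c(ea, oa))) { log["irreconcilable_alleles"] <- log["irreconcilable_alleles"] + 1L; next }
      if (palindrome_policy == "drop") { log["palindromic_dropped"] <- log["palindromic_dropped"] + 1L; next }
      if (is.na(ex$eaf[i]) || is.na(oy$eaf[i])) { log["palindromic_ambiguous"] <- log["palindromic_ambiguous"] + 1L; next }
      maf <- pmin(ex$eaf[i], 1 - ex$eaf[i])
      maf_y <- pmin(oy$eaf[i], 1 - oy$eaf[i])
      if (maf > maf_ambiguity_bound || maf_y > maf_ambiguity_bound) {
        log["palindromic_ambiguous"] <- log["palindromic_ambiguous"] + 1L; next
      }
      # frequency of the allele labelled as the outcome's effect allele:
      # same minor/major side as the exposure effect allele => aligned
      same_side <- (oy$eaf[i] < 0.5) == (ex$eaf[i] < 0.5)
      aligned <- if (ya == ea) same_side else !same_side
      if (!aligned) { beta_y[i] <- -beta_y[i]; eaf_y[i] <- 1 - eaf_y[i] }
      keep[i] <- TRUE
    } else {
      cya <- complement_allele(ya); cyb <- complement_allele(yb)
      if (ya == ea && yb == oa) {
        keep[i] <- TRUE
      } else if (ya == oa && yb == ea) {
        beta_y[i] <- -beta_y[i]; eaf_y[i] <- 1 - eaf_y[i]; keep[i] <- TRUE
      } else if (cya == ea && cyb == oa) {         # strand flip
        keep[i] <- TRUE
      } else if (cya == oa && cyb == ea) {         # strand flip + swap
        beta_y[i] <- -beta_y[i]; eaf_y[i] <- 1 - eaf_y[i]; keep[i] <- TRUE
      } else {
        log["irreconcilable_alleles"] <- log["irreconcilable_alleles"] + 1L
      }
    }
  }

  out <- data.frame(chrom = ex$chrom, pos = ex$pos, rsid = ex$rsid,
                    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
                    eaf_x = ex$eaf, beta_x = ex$beta, se_x = ex$se,
                    p_x = ex$pvalue, n_x = ex$n,
                    eaf_y = eaf_y, beta_y = beta_y, se_y = oy$se,
                    p_y = oy$pvalue, n_y = oy$n,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            outcome_type = attr(outcome, "trait_type"),
            harmonization_log = as.list(log),
            class = c("harmonized_pairs", "data.frame"))
}
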