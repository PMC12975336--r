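# Reference-panel genotype input: VCF (GT or DS fields) or a plain
# dosage table, both reduced to the samples x variants dosage matrix
# that ld_from_genotypes() consumes.

#' Read reference-panel dosages
#'
#' Accepts either a VCF (uncompressed or bgzipped; allele dosages taken
#' from the `DS` FORMAT field when present, otherwise counted from
#' `GT`) or a plain tab-delimited dosage table with variants in rows
#' (first column the variant key `chrom:pos`, remaining columns one per
#' sample). Multi-allelic VCF records are dropped with a message.
#'
#' @param path input file.
#' @param format `"auto"` (by file extension), `"vcf"` or
#'   `"dosage_table"`.
#' @return numeric matrix, samples in rows, variants (keyed
#'   `chrom:pos`) in columns — ready for [ld_from_genotypes()].
#' @export
read_dosages <- function(path, format = c("auto", "vcf", "dosage_table")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_table"
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF reference panels requires the vcfR package",
           call. = FALSE)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi)) {
      message("dropping ", sum(multi), " multi-allelic VCF record(s)")
      v <- v[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    keys <- position_key(fix[, "CHROM"], as.numeric(fix[, "POS"]))
    fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    if (all(is.na(fmt))) {
      gt <- vcfR::extract.gt(v, element = "GT")
      fmt <- apply(gt, c(1, 2), function(x) {
        if (is.na(x)) return(NA_real_)
        sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
      })
    }
    out <- t(fmt)
    colnames(out) <- keys
    storage.mode(out) <- "double"
    out
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = 1L)
    out <- t(as.matrix(tab))
    storage.mode(out) <- "double"
    out
  }
}

#' Write a dosage table
#'
#' Companion writer for the plain-text panel format accepted by
#' [read_dosages()] (variants in rows, samples in columns).
#'
#' @param genotypes samples x variants dosage matrix.
#' @param path output file.
#' @export
write_dosages <- function(genotypes, path) {
  tab <- t(genotypes)
  utils::write.table(cbind(variant = rownames(tab), as.data.frame(tab)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
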