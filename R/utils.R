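# Internal numerical helpers shared across modules.

# 95% normal quantile used for every confidence interval in the package.
Z95 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable; returns -Inf when the
# difference underflows (can happen with a single shared variant).
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Condition a correlation matrix to positive semi-definiteness
#'
#' Sample LD matrices estimated from small reference panels (a few
#' hundred haplotype donors) are frequently indefinite once subset to a
#' handful of instruments. All generalized-least-squares solves in the
#' package therefore run on an eigenvalue-floored, re-symmetrized copy
#' of the LD matrix, rescaled back to unit diagonal.
#'
#' @param r square correlation matrix.
#' @param floor smallest eigenvalue retained (default `1e-10`).
#' @return a symmetric positive semi-definite correlation matrix with
#'   unit diagonal.
#' @export
condition_psd <- function(r, floor = 1e-10) {
  r <- (r + t(r)) / 2
  if (nrow(r) == 1L) return(matrix(1, 1, 1, dimnames = dimnames(r)))
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= floor) return(r)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  out <- stats::cov2cor((out + t(out)) / 2)
  dimnames(out) <- dimnames(r)
  out
}

# Multivariate normal draws from a pre-computed upper Cholesky factor.
rmvnorm_chol <- function(n, mean, chol_upper) {
  k <- ncol(chol_upper)
  z <- matrix(stats::rnorm(n * k), n, k)
  sweep(z %*% chol_upper, 2L, mean, `+`)
}

# Deterministic sub-seed derivation: one master seed fans out to named
# analysis stages so each stage is independently reproducible. Kept
# below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629)
}

# Canonical variant key: position plus the unordered allele pair.
# rsids are advisory only; positional identity is what summary files
# reliably support.
variant_key <- function(chrom, pos, a1, a2) {
  swap <- a1 > a2
  lo <- ifelse(swap, a2, a1)
  hi <- ifelse(swap, a1, a2)
  paste(chrom, pos, lo, hi, sep = ":")
}

position_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

fmt_num <- function(x) formatC(x, digits = 8, format = "g")
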