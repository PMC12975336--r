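# Analytic power for two-sample MR with a binary outcome, and its
# inversion to the minimum detectable effect at fixed power.

#' Power of a two-sample MR test with a binary outcome
#'
#' Normal-approximation power for a two-sided Wald test of the causal
#' log-odds ratio per SD of exposure. The non-centrality parameter is
#' `NCP = n * r2 * K * (1 - K) * effect^2`, where `n` is the outcome
#' GWAS size, `K` the case fraction and `r2` the variance in the
#' exposure explained by the instruments; power is
#' `pnorm(sqrt(NCP) - z) + pnorm(-sqrt(NCP) - z)` with
#' `z = qnorm(1 - alpha/2)`. At `effect = 0` this returns `alpha`.
#'
#' @param n_outcome outcome GWAS sample size.
#' @param case_fraction case proportion in `(0, 1)`.
#' @param r2_instrument exposure variance explained by the instruments,
#'   in `[0, 1)`.
#' @param effect causal log-OR per SD of exposure (vectorized).
#' @param alpha two-sided type-I error (default 0.05).
#' @return power in `[0, 1]`.
#' @export
mr_power <- function(n_outcome, case_fraction, r2_instrument, effect,
                     alpha = 0.05) {
  stopifnot(case_fraction > 0, case_fraction < 1,
            r2_instrument >= 0, r2_instrument < 1, n_outcome > 0)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- n_outcome * r2_instrument * case_fraction * (1 - case_fraction) * effect^2
  s <- sqrt(ncp)
  stats::pnorm(s - z) + stats::pnorm(-s - z)
}

#' Minimum detectable effect at fixed power
#'
#' Inverts [mr_power()] by bisection on `|effect|` to tolerance 1e-6,
#' returning the smallest causal log-OR per SD of exposure detectable
#' with at least `target_power` — the quantity plotted in
#' detectable-estimate panels of MR power analyses.
#'
#' @inheritParams mr_power
#' @param target_power required power in `(alpha, 1)` (default 0.8).
#' @return list with `log_or`, `or = exp(log_or)`, `power` achieved,
#'   and `feasible` (`FALSE` with infinite effect when `r2 = 0`).
#' @export
detectable_effect <- function(n_outcome, case_fraction, r2_instrument,
                              alpha = 0.05, target_power = 0.8) {
  stopifnot(target_power > alpha, target_power < 1)
  if (r2_instrument <= 0)
    return(list(log_or = Inf, or = Inf, power = alpha, feasible = FALSE))
  f <- function(e) mr_power(n_outcome, case_fraction, r2_instrument, e, alpha) -
    target_power
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) < 0)
    return(list(log_or = Inf, or = Inf, power = alpha, feasible = FALSE))
  root <- stats::uniroot(f, c(0, hi), tol = 1e-6)$root
  list(log_or = root, or = exp(root),
       power = mr_power(n_outcome, case_fraction, r2_instrument, root, alpha),
       feasible = TRUE)
}

#' Detectable-effect grid
#'
#' Tabulates the minimum detectable OR over sample-size and
#' instrument-strength settings, e.g. one row per ancestry-specific
#' outcome GWAS.
#'
#' @param settings data.frame with columns `label`, `n_outcome`,
#'   `case_fraction`, `r2_instrument`.
#' @inheritParams detectable_effect
#' @return the input with `detectable_log_or`, `detectable_or` columns.
#' @export
power_grid <- function(settings, alpha = 0.05, target_power = 0.8) {
  res <- lapply(seq_len(nrow(settings)), function(i)
    detectable_effect(settings$n_outcome[i], settings$case_fraction[i],
                      settings$r2_instrument[i], alpha, target_power))
  settings$detectable_log_or <- vapply(res, `[[`, 0, "log_or")
  settings$detectable_or <- vapply(res, `[[`, 0, "or")
  settings
}
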