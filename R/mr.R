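# Two-sample MR estimators for correlated instruments: Wald ratio,
# generalized (LD-aware) IVW, MR-Egger, Cochran's Q, multivariable MR.
#
# All GLS solves use Omega = D %*% rho %*% D with D = diag(se_y): the
# outcome-side covariance under the NOME assumption (exposure-side
# uncertainty is ignored in the weights, the standard first-order
# treatment).

mr_estimate <- function(method, theta, se, n_snps,
                        q_stat = NA_real_, q_pvalue = NA_real_,
                        egger_intercept = NA_real_, intercept_se = NA_real_,
                        model = NA_character_, exposure_id = NA_character_,
                        outcome_id = NA_character_, outcome_type = "quantitative") {
  theta <- unname(theta); se <- unname(se)
  egger_intercept <- unname(egger_intercept); intercept_se <- unname(intercept_se)
  z <- theta / se
  structure(list(method = method, theta = theta, se = se,
                 ci_low = theta - Z95 * se, ci_high = theta + Z95 * se,
                 pvalue = 2 * stats::pnorm(-abs(z)),
                 n_snps = n_snps, q_stat = q_stat, q_pvalue = q_pvalue,
                 egger_intercept = egger_intercept, intercept_se = intercept_se,
                 model = model, exposure_id = exposure_id,
                 outcome_id = outcome_id, outcome_type = outcome_type),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s%s]: theta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, %d SNP(s)\n",
              x$method, if (!is.na(x$model)) paste0(", ", x$model) else "",
              x$theta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snps))
  if (identical(x$outcome_type, "binary"))
    cat(sprintf("  OR = %.3f [%.3f, %.3f]\n",
                exp(x$theta), exp(x$ci_low), exp(x$ci_high)))
  if (!is.na(x$q_stat))
    cat(sprintf("  Cochran's Q = %.3f (p = %.3g)\n", x$q_stat, x$q_pvalue))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (SE %.4f)\n",
                x$egger_intercept, x$intercept_se))
  invisible(x)
}

#' Tidy one or several MR estimates into a data.frame
#' @param estimates an `mr_estimate` or list of them.
#' @return data.frame, one row per estimate.
#' @export
tidy_mr <- function(estimates) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e)
    data.frame(method = e$method, model = e$model,
               exposure = e$exposure_id, outcome = e$outcome_id,
               theta = e$theta, se = e$se, ci_low = e$ci_low,
               ci_high = e$ci_high, pvalue = e$pvalue, n_snps = e$n_snps,
               q_stat = e$q_stat, q_pvalue = e$q_pvalue,
               or = if (identical(e$outcome_type, "binary")) exp(e$theta) else NA_real_,
               stringsAsFactors = FALSE)))
}

#' Wald ratio estimator
#'
#' Single-variant causal estimate `beta_y / beta_x`. The default
#' standard error is the first-order delta approximation
#' `se_y / |beta_x|`; `second_order = TRUE` adds the exposure-side term
#' `beta_y^2 se_x^2 / beta_x^4`, which can only enlarge the SE.
#'
#' @param beta_x,se_x variant-exposure effect and SE.
#' @param beta_y,se_y variant-outcome effect and SE.
#' @param second_order include the exposure-uncertainty term.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (beta_x == 0) stop("beta_x is zero: Wald ratio undefined", call. = FALSE)
  theta <- beta_y / beta_x
  se <- se_y / abs(beta_x)
  if (second_order)
    se <- sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  mr_estimate("wald", theta, se, n_snps = 1L, model = "fixed")
}

build_omega <- function(inst) {
  d <- inst$se_y
  outer(d, d) * inst$ld
}

#' Generalized inverse-variance-weighted estimator for correlated instruments
#'
#' GLS regression of the variant-outcome effects on the
#' variant-exposure effects through the origin, weighting by the inverse
#' of `Omega = diag(se_y) %*% rho %*% diag(se_y)` where `rho` is the
#' reference-panel LD correlation. With identity LD this is the textbook
#' IVW estimator; with a single variant it reduces to the Wald ratio.
#'
#' Under `model = "multiplicative_random"` the fixed-effect SE is
#' inflated by `max(1, sqrt(Q / (n - 1)))`. The default keeps a fixed
#' model for up to 3 instruments and switches to the multiplicative
#' random-effects model beyond that.
#'
#' @param instruments an [instrument_set()].
#' @param model `"default"`, `"fixed"` or `"multiplicative_random"`.
#' @return an `mr_estimate` carrying the generalized Cochran's Q.
#' @export
ivw_correlated <- function(instruments,
                           model = c("default", "fixed", "multiplicative_random")) {
  model <- match.arg(model)
  n <- n_instruments(instruments)
  if (n < 1L) stop("need at least one instrument", call. = FALSE)
  bx <- drop(instruments$beta_x)
  if (!is.null(dim(bx)) || NCOL(instruments$beta_x) > 1L)
    stop("ivw_correlated is univariable; use mvmr_correlated", call. = FALSE)
  by <- instruments$beta_y
  omega <- build_omega(instruments)
  oi_bx <- tryCatch(solve(omega, bx), error = function(e)
    stop("outcome covariance is singular after PSD conditioning: ",
         conditionMessage(e), call. = FALSE))
  denom <- sum(bx * oi_bx)
  theta <- sum(oi_bx * by) / denom
  se_fixed <- sqrt(1 / denom)
  if (model == "default")
    model <- if (n <= 3L) "fixed" else "multiplicative_random"
  q <- q_p <- NA_real_
  if (n >= 2L) {
    qq <- cochran_q(instruments, theta)
    q <- qq[["q_stat"]]; q_p <- qq[["q_pvalue"]]
  }
  se <- if (model == "multiplicative_random" && n >= 2L)
    se_fixed * max(1, sqrt(q / (n - 1))) else se_fixed
  mr_estimate("ivw_correlated", theta, se, n_snps = n, q_stat = q,
              q_pvalue = q_p, model = model,
              exposure_id = instruments$exposure_ids[1],
              outcome_id = instruments$outcome_id,
              outcome_type = instruments$outcome_type)
}

orient_positive_bx <- function(inst) {
  s <- ifelse(inst$beta_x[, 1] < 0, -1, 1)
  inst$beta_x <- inst$beta_x * s
  inst$beta_y <- inst$beta_y * s
  inst$ld <- inst$ld * outer(s, s)
  inst
}

#' MR-Egger regression for correlated instruments
#'
#' GLS fit of the variant-outcome effects on an intercept plus the
#' variant-exposure effects, after orienting every variant so its
#' exposure effect is non-negative (outcome effects and LD signs
#' co-flipped). The slope is the pleiotropy-robust causal estimate; a
#' non-zero intercept indicates directional pleiotropy.
#'
#' @inheritParams ivw_correlated
#' @return an `mr_estimate` with `egger_intercept` and `intercept_se`.
#' @export
mr_egger_correlated <- function(instruments,
                                model = c("default", "fixed", "multiplicative_random")) {
  model <- match.arg(model)
  n <- n_instruments(instruments)
  if (n < 3L) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  inst <- orient_positive_bx(instruments)
  bx <- as.vector(inst$beta_x[, 1])
  by <- inst$beta_y
  omega <- build_omega(inst)
  x <- cbind(intercept = 1, slope = bx)
  oi_x <- solve(omega, x)
  info <- crossprod(x, oi_x)
  coefs <- solve(info, crossprod(oi_x, by))
  vcov <- solve(info)
  resid <- by - x %*% coefs
  q <- drop(crossprod(resid, solve(omega, resid)))
  q_p <- stats::pchisq(q, df = n - 2L, lower.tail = FALSE)
  if (model == "default")
    model <- if (n <= 3L) "fixed" else "multiplicative_random"
  infl <- if (model == "multiplicative_random") max(1, sqrt(q / (n - 2L))) else 1
  mr_estimate("egger", coefs["slope", 1], sqrt(vcov["slope", "slope"]) * infl,
              n_snps = n, q_stat = q, q_pvalue = q_p,
              egger_intercept = coefs["intercept", 1],
              intercept_se = sqrt(vcov["intercept", "intercept"]) * infl,
              model = model,
              exposure_id = instruments$exposure_ids[1],
              outcome_id = instruments$outcome_id,
              outcome_type = instruments$outcome_type)
}

#' Generalized Cochran's Q heterogeneity statistic
#'
#' `Q = (beta_y - theta * beta_x)' Omega^-1 (beta_y - theta * beta_x)`,
#' compared to a chi-square with `n_snps - 1` degrees of freedom. With
#' identity LD this reduces to the familiar sum of squared standardized
#' residuals.
#'
#' @param instruments an [instrument_set()].
#' @param theta causal-effect value the residuals are taken about.
#' @return named vector `c(q_stat, q_pvalue)`.
#' @export
cochran_q <- function(instruments, theta) {
  n <- n_instruments(instruments)
  if (n < 2L) stop("Cochran's Q needs at least 2 instruments", call. = FALSE)
  resid <- instruments$beta_y - theta * as.vector(instruments$beta_x[, 1])
  omega <- build_omega(instruments)
  q <- drop(crossprod(resid, solve(omega, resid)))
  c(q_stat = q, q_pvalue = stats::pchisq(q, df = n - 1L, lower.tail = FALSE))
}

#' Multivariable MR with correlated instruments
#'
#' Joint GLS solve
#' `theta = (Bx' Omega^-1 Bx)^-1 Bx' Omega^-1 beta_y` over `k` exposure
#' columns; per-exposure SEs come from the diagonal of the inverse
#' information. Used to adjust mediator effects for the drug-target
#' gene region (the mediator and the target exposure entering jointly).
#'
#' @param instruments an [instrument_set()] whose `beta_x` has `k`
#'   columns.
#' @param model variance model as in [ivw_correlated()].
#' @return list of `k` `mr_estimate` objects, one per exposure column.
#' @export
mvmr_correlated <- function(instruments,
                            model = c("default", "fixed", "multiplicative_random")) {
  model <- match.arg(model)
  bx <- instruments$beta_x
  k <- ncol(bx)
  n <- n_instruments(instruments)
  if (n < k) stop("need at least as many instruments as exposures", call. = FALSE)
  if (qr(bx)$rank < k)
    stop("exposure design is rank deficient (collinear exposure columns)",
         call. = FALSE)
  omega <- build_omega(instruments)
  oi_bx <- solve(omega, bx)
  info <- crossprod(bx, oi_bx)
  theta <- solve(info, crossprod(oi_bx, instruments$beta_y))
  vcov <- solve(info)
  resid <- instruments$beta_y - bx %*% theta
  q <- drop(crossprod(resid, solve(omega, resid)))
  df_q <- n - k
  q_p <- if (df_q > 0) stats::pchisq(q, df = df_q, lower.tail = FALSE) else NA_real_
  if (model == "default")
    model <- if (n <= 3L) "fixed" else "multiplicative_random"
  infl <- if (model == "multiplicative_random" && df_q > 0) max(1, sqrt(q / df_q)) else 1
  lapply(seq_len(k), function(j)
    mr_estimate("mvmr", theta[j, 1], sqrt(vcov[j, j]) * infl, n_snps = n,
                q_stat = q, q_pvalue = q_p, model = model,
                exposure_id = instruments$exposure_ids[j],
                outcome_id = instruments$outcome_id,
                outcome_type = instruments$outcome_type))
}
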