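test_that("Wald ratio follows the delta method", {
  w <- wald_ratio(beta_x = 0.1, se_x = 0.02, beta_y = 0.05, se_y = 0.01)
  expect_equal(w$theta, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(w$ci_low, w$theta - 1.959964 * w$se, tolerance = 1e-9)
  w0 <- wald_ratio(0.1, 0.02, 0, 0.01)
  expect_equal(w0$theta, 0)
  expect_equal(w0$pvalue, 1)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.01), "zero")
  # second-order SE dominates the first-order SE
  set.seed(1)
  for (i in 1:20) {
    bx <- runif(1, 0.05, 1); sx <- runif(1, 0.01, 0.2)
    by <- rnorm(1); sy <- runif(1, 0.01, 0.2)
    expect_gte(wald_ratio(bx, sx, by, sy, second_order = TRUE)$se,
               wald_ratio(bx, sx, by, sy)$se)
  }
})

test_that("correlated IVW reduces to the textbook estimator and Wald ratio", {
  # single SNP: identical to the Wald ratio
  inst1 <- make_instruments(0.1, 0.02, 0.05, 0.01)
  e1 <- ivw_correlated(inst1)
  w1 <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(e1$theta, w1$theta, tolerance = 1e-12)
  expect_equal(e1$se, w1$se, tolerance = 1e-12)

  # closed form with unit weights
  e2 <- ivw_correlated(make_instruments(c(1, 1), c(0.1, 0.1), c(1, 3), c(1, 1)),
                       model = "fixed")
  expect_equal(e2$theta, 2)
  expect_equal(e2$se, 1 / sqrt(2))

  # identity LD equals the textbook IVW to 1e-10
  set.seed(2)
  bx <- runif(8, 0.05, 0.3); by <- 0.4 * bx + rnorm(8, 0, 0.02)
  sy <- runif(8, 0.01, 0.05)
  e3 <- ivw_correlated(make_instruments(bx, bx * 0.1, by, sy), model = "fixed")
  o3 <- textbook_ivw(bx, by, sy)
  expect_equal(e3$theta, o3$theta, tolerance = 1e-10)
  expect_equal(e3$se, o3$se, tolerance = 1e-10)

  # perfectly duplicated SNP collapses to the single-SNP estimate
  rho <- matrix(c(1, 1, 1, 1), 2, 2)
  dup <- make_instruments(c(0.2, 0.2), c(0.02, 0.02), c(0.08, 0.08),
                          c(0.01, 0.01), rho = rho)
  ed <- ivw_correlated(dup, model = "fixed")
  es <- ivw_correlated(make_instruments(0.2, 0.02, 0.08, 0.01))
  expect_equal(ed$theta, es$theta, tolerance = 1e-6)
  expect_equal(ed$se, es$se, tolerance = 1e-4)
})

test_that("IVW is scale equivariant and model selection follows instrument count", {
  set.seed(3)
  bx <- runif(6, 0.1, 0.3); by <- 0.3 * bx + rnorm(6, 0, 0.01)
  sy <- runif(6, 0.01, 0.03)
  inst <- make_instruments(bx, bx * 0.1, by, sy)
  base <- ivw_correlated(inst, model = "fixed")
  scaled <- make_instruments(3 * bx, 3 * bx * 0.1, by, sy)
  expect_equal(ivw_correlated(scaled, model = "fixed")$theta, base$theta / 3,
               tolerance = 1e-12)
  expect_equal(ivw_correlated(inst)$model, "multiplicative_random")
  inst3 <- make_instruments(bx[1:3], bx[1:3] * 0.1, by[1:3], sy[1:3])
  expect_equal(ivw_correlated(inst3)$model, "fixed")
})

test_that("MR-Egger handles degenerate and oriented inputs", {
  # constant outcome effects: slope ~ 0, intercept ~ the constant
  bx <- c(0.1, 0.2, 0.3, 0.4)
  inst <- make_instruments(bx, bx * 0.1, rep(0.07, 4), rep(0.01, 4))
  e <- mr_egger_correlated(inst, model = "fixed")
  expect_equal(e$theta, 0, tolerance = 1e-8)
  expect_equal(e$egger_intercept, 0.07, tolerance = 1e-8)

  # flipping one variant's orientation leaves the fit invariant
  flipped <- make_instruments(c(-bx[1], bx[2:4]), bx * 0.1,
                              c(-0.07, rep(0.07, 3)), rep(0.01, 4))
  ef <- mr_egger_correlated(flipped, model = "fixed")
  expect_equal(ef$theta, e$theta, tolerance = 1e-10)
  expect_equal(ef$egger_intercept, e$egger_intercept, tolerance = 1e-10)

  expect_error(mr_egger_correlated(make_instruments(bx[1:2], c(0.01, 0.01),
                                                    c(0.1, 0.1), c(0.01, 0.01))),
               "at least 3")
})

test_that("Egger intercept CI covers zero at the nominal rate without pleiotropy", {
  set.seed(4)
  n_reps <- 300; k <- 50
  bx <- runif(k, 0.1, 0.5)
  sy <- rep(0.05, k)
  cover <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    by <- 0.5 * bx + rnorm(k, 0, sy)
    e <- mr_egger_correlated(make_instruments(bx, bx * 0.05, by, sy),
                             model = "fixed")
    cover[r] <- abs(e$egger_intercept) < 1.959964 * e$intercept_se
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("generalized Cochran's Q behaves like its identity-LD reduction", {
  bx <- c(0.1, 0.2, 0.3); sy <- c(0.01, 0.02, 0.015)
  # exact fit: Q = 0, p = 1
  inst0 <- make_instruments(bx, bx * 0.1, 0.4 * bx, sy)
  q0 <- cochran_q(inst0, 0.4)
  expect_equal(unname(q0["q_stat"]), 0, tolerance = 1e-18)
  expect_equal(unname(q0["q_pvalue"]), 1)
  # identity LD reduces to the weighted residual sum of squares
  by <- c(0.05, 0.07, 0.14)
  inst <- make_instruments(bx, bx * 0.1, by, sy)
  q <- cochran_q(inst, 0.4)
  expect_equal(unname(q["q_stat"]), sum((by - 0.4 * bx)^2 / sy^2),
               tolerance = 1e-10)
})

test_that("multivariable MR matches univariable IVW and flags collinearity", {
  set.seed(5)
  bx <- runif(6, 0.1, 0.4); by <- 0.25 * bx + rnorm(6, 0, 0.01)
  sy <- rep(0.02, 6)
  inst <- make_instruments(bx, bx * 0.1, by, sy)
  m1 <- mvmr_correlated(inst, model = "fixed")
  expect_length(m1, 1L)
  expect_equal(m1[[1]]$theta, ivw_correlated(inst, model = "fixed")$theta,
               tolerance = 1e-12)

  dup <- inst
  dup$beta_x <- cbind(a = bx, b = bx)
  dup$se_x <- cbind(a = bx * 0.1, b = bx * 0.1)
  dup$exposure_ids <- c("a", "b")
  expect_error(mvmr_correlated(dup), "rank deficient")
})

test_that("a null orthogonal exposure column is covered at the nominal rate", {
  set.seed(6)
  n_reps <- 300; k <- 20
  bx1 <- runif(k, 0.1, 0.4)
  bx2 <- runif(k, 0.1, 0.4)  # no effect on outcome
  sy <- rep(0.03, k)
  cover <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    by <- 0.3 * bx1 + rnorm(k, 0, sy)
    inst <- make_instruments(bx1, bx1 * 0.05, by, sy)
    inst$beta_x <- cbind(x1 = bx1, x2 = bx2)
    inst$se_x <- cbind(x1 = bx1 * 0.05, x2 = bx2 * 0.05)
    inst$exposure_ids <- c("x1", "x2")
    fit <- mvmr_correlated(inst, model = "fixed")[[2]]
    cover[r] <- fit$ci_low <= 0 && fit$ci_high >= 0
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
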