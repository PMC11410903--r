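# Wald ratios, IVW (independent and correlated), weighted median, Egger.

test_that("Wald ratios follow the delta-method formula and its symmetries", {
  h <- make_harmonized(g = 0.4, G = 0.2, se_G = 0.05)
  w <- wald_ratio(h)
  expect_equal(w$theta, 0.5)
  expect_equal(w$theta_se, 0.125)

  h1 <- make_harmonized(g = 1, G = 0.3, se_G = 0.07)
  w1 <- wald_ratio(h1)
  expect_equal(w1$theta, 0.3)
  expect_equal(w1$theta_se, 0.07)

  hneg <- make_harmonized(g = -0.4, G = -0.2, se_G = 0.05)
  expect_equal(wald_ratio(hneg)$theta, 0.5)

  h0 <- make_harmonized(g = 0, G = 0.1, se_G = 0.05)
  expect_error(wald_ratio(h0), "degenerate")
})

test_that("single-instrument IVW reduces to the Wald ratio", {
  h <- make_harmonized(g = 0.4, G = 0.2, se_G = 0.05)
  e <- mr_ivw(h)
  w <- wald_ratio(h)
  expect_equal(e$slope, w$theta)
  expect_equal(e$se, w$theta_se)
  expect_equal(e$method, "wald")
  expect_true(is.na(e$q_statistic))
  expect_warning(mr_ivw(h, effects_model = "random"), "fixed")
})

test_that("homogeneous instruments give zero Q and no random-effects inflation", {
  h <- make_harmonized(g = c(0.2, 0.4), G = c(0.1, 0.2), se_G = c(0.03, 0.06))
  ef <- mr_ivw(h, effects_model = "fixed")
  er <- mr_ivw(h, effects_model = "random")
  expect_equal(ef$slope, 0.5)
  expect_equal(ef$q_statistic, 0)
  expect_equal(er$se, ef$se)
})

test_that("the auto rule switches from fixed to random at four instruments", {
  h3 <- make_harmonized(g = rep(0.2, 3), G = c(0.1, 0.2, 0.05), se_G = 0.02)
  h4 <- make_harmonized(g = rep(0.2, 4), G = c(0.1, 0.2, 0.05, 0.3), se_G = 0.02)
  expect_equal(mr_ivw(h3)$effects_model, "fixed")
  expect_equal(mr_ivw(h4)$effects_model, "random")
  expect_gte(mr_ivw(h4)$se, mr_ivw(h4, effects_model = "fixed")$se)
})

test_that("IVW matches an independent weighted-least-squares solve", {
  set.seed(101)
  for (rep in 1:20) {
    J <- sample(3:12, 1)
    h <- make_harmonized(g = runif(J, 0.05, 0.4) * sign(runif(J, -1, 1)),
                         G = rnorm(J, 0, 0.1), se_G = runif(J, 0.01, 0.1))
    fit <- mr_ivw(h, effects_model = "fixed")
    # oracle: explicit normal-equations solve of the origin regression
    X <- matrix(h$exposure_beta, ncol = 1)
    Wm <- diag(1 / h$outcome_se^2)
    slope_o <- solve(t(X) %*% Wm %*% X, t(X) %*% Wm %*% h$outcome_beta)
    se_o <- sqrt(solve(t(X) %*% Wm %*% X))
    expect_equal(fit$slope, drop(slope_o), tolerance = 1e-12)
    expect_equal(fit$se, drop(se_o), tolerance = 1e-12)
  }
})

test_that("identity LD reproduces the uncorrelated IVW exactly", {
  set.seed(7)
  J <- 6
  h <- make_harmonized(g = runif(J, 0.1, 0.3), G = rnorm(J, 0.05, 0.05),
                       se_G = runif(J, 0.02, 0.08))
  ld <- ld_matrix(diag(J), h$variant_id)
  a <- mr_ivw(h)
  b <- mr_ivw_correlated(h, ld)
  expect_equal(b$slope, a$slope, tolerance = 1e-10)
  expect_equal(b$se, a$se, tolerance = 1e-6)
  expect_equal(b$q_statistic, a$q_statistic, tolerance = 1e-6)
})

test_that("near-duplicate instruments collapse to a single Wald ratio", {
  h <- make_harmonized(g = c(0.2, 0.2), G = c(0.1, 0.1), se_G = c(0.05, 0.05))
  ld <- ld_matrix(matrix(c(1, 1 - 1e-9, 1 - 1e-9, 1), 2), h$variant_id)
  e <- mr_ivw_correlated(h, ld, effects_model = "fixed")
  single <- mr_ivw(h[1, ], effects_model = "fixed")
  expect_equal(e$slope, single$slope, tolerance = 1e-6)
  expect_gte(e$se, single$se * (1 - 1e-3))
})

test_that("correlated IVW matches a generic GLS solve under AR(1) LD", {
  set.seed(11)
  J <- 5
  h <- make_harmonized(g = runif(J, 0.1, 0.4), G = rnorm(J, 0.1, 0.05),
                       se_G = runif(J, 0.02, 0.06))
  rho <- 0.5^abs(outer(1:J, 1:J, "-"))
  ld <- ld_matrix(rho, h$variant_id)
  fit <- mr_ivw_correlated(h, ld, effects_model = "fixed")
  # oracle: whiten by the inverse Cholesky factor and run OLS through origin
  omega <- outer(h$outcome_se, h$outcome_se) * rho
  Li <- solve(t(chol(omega)))
  ystar <- drop(Li %*% h$outcome_beta)
  xstar <- drop(Li %*% h$exposure_beta)
  ols <- lm(ystar ~ 0 + xstar)
  expect_equal(fit$slope, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$se, 1 / sqrt(sum(xstar^2)), tolerance = 1e-6)
})

test_that("a non-positive-definite weighting matrix is reported as such", {
  h <- make_harmonized(g = c(0.2, 0.2, 0.2), G = c(0.1, 0.1, 0.1), se_G = 0.05)
  bad <- matrix(1, 3, 3)
  bad[1, 3] <- bad[3, 1] <- -1
  ld <- structure(bad, dimnames = list(h$variant_id, h$variant_id),
                  class = c("ld_matrix", "matrix", "array"))
  expect_error(mr_ivw_correlated(h, ld), "positive definite")
})

test_that("weighted median interpolates at half the weight", {
  h <- make_harmonized(g = rep(1, 3), G = c(1, 2, 3), se_G = rep(1, 3))
  e <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(e$slope, 2)

  same <- make_harmonized(g = rep(0.5, 5), G = rep(0.2, 5), se_G = 1e-5)
  es <- mr_weighted_median(same, n_boot = 100, seed = 1)
  expect_equal(es$slope, 0.4)
  expect_lt(es$se, 1e-3)
  expect_error(mr_weighted_median(h[1:2, ]), "at least 3")
})

test_that("weighted median resists a minority of pleiotropic outliers", {
  set.seed(21)
  J <- 50
  g <- runif(J, 0.1, 0.3)
  slope <- rep(0.5, J); slope[1:10] <- 5
  se_G <- rep(0.02, J)
  h <- make_harmonized(g = g, G = slope * g + rnorm(J, 0, se_G), se_G = se_G)
  wm <- mr_weighted_median(h, n_boot = 200, seed = 2)
  ivw <- mr_ivw(h)
  expect_lt(abs(wm$slope - 0.5), 0.1)
  expect_gt(ivw$slope - 0.5, 4 * abs(wm$slope - 0.5))  # IVW dragged upward
})

test_that("Egger behaves as a weighted linear model after orientation", {
  set.seed(31)
  J <- 10
  g <- runif(J, 0.1, 0.4) * sign(runif(J, -1, 1))
  G <- 0.3 * g + rnorm(J, 0, 0.02)
  h <- make_harmonized(g = g, G = G, se_G = rep(0.02, J))
  e <- mr_egger(h, effects_model = "fixed")
  # adding a constant to every oriented outcome effect shifts only the intercept
  flip <- sign(h$exposure_beta)
  h2 <- h
  h2$outcome_beta <- h$outcome_beta + flip * 0.05  # +0.05 after orientation
  e2 <- mr_egger(h2, effects_model = "fixed")
  expect_equal(e2$slope, e$slope, tolerance = 1e-9)
  expect_equal(e2$egger_intercept, e$egger_intercept + 0.05, tolerance = 1e-9)
  # identity-LD GLS equals the weighted fit
  eg <- mr_egger(h, ld = ld_matrix(diag(J), h$variant_id),
                 effects_model = "fixed")
  expect_equal(eg$slope, e$slope, tolerance = 1e-8)
  expect_equal(eg$egger_intercept_se, e$egger_intercept_se, tolerance = 1e-6)
  # oracle: lm with analytic weights reproduces slope/intercept
  or <- lm(flip * h$outcome_beta ~ I(flip * h$exposure_beta),
           weights = 1 / h$outcome_se^2)
  expect_equal(e$slope, unname(coef(or)[2]), tolerance = 1e-9)
  expect_equal(e$egger_intercept, unname(coef(or)[1]), tolerance = 1e-9)
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("estimators are invariant to instrument relabeling", {
  set.seed(41)
  J <- 8
  h <- make_harmonized(g = runif(J, 0.1, 0.4), G = rnorm(J, 0.1, 0.05),
                       se_G = runif(J, 0.02, 0.06))
  perm <- sample(J)
  hp <- h[perm, ]
  ld <- ld_matrix(0.4^abs(outer(1:J, 1:J, "-")), h$variant_id)
  expect_equal(mr_ivw(hp)$slope, mr_ivw(h)$slope)
  expect_equal(mr_ivw_correlated(hp, ld)$slope,
               mr_ivw_correlated(h, ld)$slope, tolerance = 1e-10)
  expect_equal(mr_egger(hp)$slope, mr_egger(h)$slope, tolerance = 1e-10)
  expect_equal(mr_weighted_median(hp, n_boot = 10, seed = 1)$slope,
               mr_weighted_median(h, n_boot = 10, seed = 1)$slope)
})

test_that("lowering orientation mirrors the estimate and is an involution", {
  h <- make_harmonized(g = rep(0.2, 4), G = c(-0.05, -0.07, -0.06, -0.04),
                       se_G = 0.02)
  e <- mr_ivw(h)
  low <- lowering_orientation(e)
  expect_equal(low$slope, -e$slope)
  expect_equal(low$ci_low, -e$ci_high)
  expect_equal(low$ci_high, -e$ci_low)
  expect_equal(low$p_value, e$p_value)
  expect_equal(low$q_statistic, e$q_statistic)
  expect_equal(low$orientation, "lowering")
  expect_equal(lowering_orientation(low)$slope, e$slope)
  zero <- make_estimate(0, 0.1)
  expect_equal(lowering_orientation(zero)$slope, 0)
  expect_equal(odds_ratio(low)$or, exp(low$slope))
})
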