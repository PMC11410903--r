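# Causal-effect estimators for summary-data Mendelian randomization.
#
# Notation: gamma_j / se_gamma_j are the variant-exposure associations,
# Gamma_j / se_Gamma_j the variant-outcome associations, theta_j the
# per-variant Wald ratio. First-order weights (exposure error ignored) are
# used throughout, the convention for summary-data MR.

.mr_estimate <- function(method, slope, se, n_snps,
                         q_statistic = NA_real_, q_df = NA_real_,
                         egger_intercept = NA_real_,
                         egger_intercept_se = NA_real_,
                         effects_model = NA_character_,
                         orientation = "raising") {
  z <- slope / se
  est <- list(
    method = method,
    slope = slope, se = se,
    ci_low = slope - stats::qnorm(0.975) * se,
    ci_high = slope + stats::qnorm(0.975) * se,
    p_value = 2 * stats::pnorm(-abs(z)),
    n_snps = n_snps,
    q_statistic = q_statistic,
    q_p_value = if (is.na(q_statistic) || is.na(q_df) || q_df < 1) NA_real_
                else stats::pchisq(q_statistic, df = q_df, lower.tail = FALSE),
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = if (is.na(egger_intercept)) NA_real_
                        else 2 * stats::pnorm(-abs(egger_intercept / egger_intercept_se)),
    effects_model = effects_model,
    orientation = orientation
  )
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("MR estimate [%s, %s orientation]\n", x$method, x$orientation))
  cat(sprintf("  slope % .4g (se %.4g), 95%% CI [% .4g, % .4g], p = %.3g, J = %d\n",
              x$slope, x$se, x$ci_low, x$ci_high, x$p_value, x$n_snps))
  if (!is.na(x$q_statistic)) {
    cat(sprintf("  Q = %.4g (p = %.3g)\n", x$q_statistic, x$q_p_value))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  intercept % .4g (se %.4g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

.check_harmonized <- function(h) {
  stopifnot(inherits(h, "data.frame"))
  need <- c("variant_id", "exposure_beta", "exposure_se", "outcome_beta", "outcome_se")
  if (!all(need %in% names(h))) {
    stop("expected harmonized instruments with columns: ",
         paste(need, collapse = ", "))
  }
  if (inherits(h, "harmonized_instruments")) h <- retained(h)
  if (nrow(h) == 0) stop("no retained instruments")
  if (any(h$exposure_se <= 0) || any(h$outcome_se <= 0)) {
    stop("standard errors must be positive")
  }
  h
}

#' Variant-level Wald ratios
#'
#' The per-variant causal estimate: outcome association divided by exposure
#' association, with the first-order (delta-method) standard error
#' `se(Gamma) / |gamma|`.
#'
#' @param h harmonized instruments ([harmonize()] output or any data.frame
#'   with the exposure/outcome beta and se columns).
#' @return data.frame of class `ratio_estimates` with columns `variant_id`,
#'   `theta`, `theta_se`.
#' @export
wald_ratio <- function(h) {
  h <- .check_harmonized(h)
  if (any(h$exposure_beta == 0)) {
    stop("degenerate instrument: exposure association is exactly zero for ",
         paste(h$variant_id[h$exposure_beta == 0], collapse = ", "))
  }
  out <- data.frame(
    variant_id = h$variant_id,
    theta = h$outcome_beta / h$exposure_beta,
    theta_se = h$outcome_se / abs(h$exposure_beta),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ratio_estimates", "data.frame")
  out
}

.resolve_effects_model <- function(effects_model, J) {
  effects_model <- match.arg(effects_model, c("auto", "fixed", "random"))
  if (effects_model == "auto") {
    # fixed effects for three variants or fewer, random for four or more
    effects_model <- if (J <= 3) "fixed" else "random"
  }
  if (effects_model == "random" && J < 2) {
    warning("random-effects scaling needs at least 2 instruments; using fixed")
    effects_model <- "fixed"
  }
  effects_model
}

#' Inverse-variance-weighted estimate (uncorrelated instruments)
#'
#' Weighted regression of outcome on exposure associations through the
#' origin with first-order weights `1/se(Gamma)^2`. The `auto` effects model
#' follows the three-or-fewer / four-or-more rule: fixed effects up to three
#' instruments, multiplicative random effects (variance inflation floored at
#' 1) from four.
#'
#' @param h harmonized instruments.
#' @param effects_model `"auto"`, `"fixed"` or `"random"`.
#' @return An `mr_estimate` with Cochran's Q on `J - 1` degrees of freedom.
#' @export
mr_ivw <- function(h, effects_model = "auto") {
  h <- .check_harmonized(h)
  J <- nrow(h)
  effects_model <- .resolve_effects_model(effects_model, J)
  g <- h$exposure_beta; G <- h$outcome_beta; w <- 1 / h$outcome_se^2
  sw <- sum(g^2 * w)
  slope <- sum(g * G * w) / sw
  se_fixed <- 1 / sqrt(sw)
  Q <- sum(w * (G - slope * g)^2)
  se <- se_fixed
  if (effects_model == "random") {
    se <- se_fixed * max(1, sqrt(Q / (J - 1)))
  }
  .mr_estimate(if (J == 1) "wald" else paste0("ivw_", effects_model),
               slope, se, J,
               q_statistic = if (J > 1) Q else NA_real_, q_df = J - 1,
               effects_model = effects_model)
}

# Inverse of the GLS weighting matrix Omega = D rho D (D = diag of outcome
# se). A diagonal ridge is applied only when the plain Cholesky fails, so
# well-conditioned inputs are inverted exactly.
.omega_inverse <- function(outcome_se, rho, ridge = 1e-8) {
  omega <- outer(outcome_se, outcome_se) * rho
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) {
    diag(omega) <- diag(omega) + ridge
    ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0) {
      stop(sprintf("weighting matrix not positive definite (min eigenvalue %.3g)",
                   ev_min))
    }
    ch <- chol(omega)
  }
  chol2inv(ch)
}

.align_ld <- function(h, ld) {
  missing <- setdiff(h$variant_id, rownames(ld))
  if (length(missing) > 0) {
    stop("LD matrix does not cover instrument(s): ",
         paste(missing, collapse = ", "))
  }
  unclass(ld)[h$variant_id, h$variant_id, drop = FALSE]
}

#' IVW for LD-correlated instruments
#'
#' Generalized weighted least squares through the origin with weighting
#' matrix `Omega[i, j] = se(Gamma_i) se(Gamma_j) rho[i, j]`, the extension
#' of [mr_ivw()] that accounts for correlation between instruments.
#' Reduces to [mr_ivw()] when `rho` is the identity.
#'
#' @param h harmonized instruments.
#' @param ld [ld_matrix()] covering the instruments (signed r, aligned to
#'   the harmonized effect alleles).
#' @param effects_model `"auto"`, `"fixed"` or `"random"`.
#' @return An `mr_estimate` with the generalized Q statistic.
#' @export
mr_ivw_correlated <- function(h, ld, effects_model = "auto") {
  h <- .check_harmonized(h)
  J <- nrow(h)
  effects_model <- .resolve_effects_model(effects_model, J)
  rho <- .align_ld(h, ld)
  g <- h$exposure_beta; G <- h$outcome_beta
  oi <- .omega_inverse(h$outcome_se, rho)
  gog <- drop(crossprod(g, oi %*% g))
  slope <- drop(crossprod(g, oi %*% G)) / gog
  se_fixed <- sqrt(1 / gog)
  resid <- G - slope * g
  Q <- drop(crossprod(resid, oi %*% resid))
  se <- se_fixed
  if (effects_model == "random") se <- se_fixed * max(1, sqrt(Q / (J - 1)))
  .mr_estimate(paste0("ivw_", effects_model), slope, se, J,
               q_statistic = if (J > 1) Q else NA_real_, q_df = J - 1,
               effects_model = effects_model)
}

#' Weighted-median estimate
#'
#' The weighted median of the variant-level Wald ratios with weights
#' proportional to `gamma^2 / se(Gamma)^2`, interpolated at cumulative
#' weight one half using midpoint cumulative sums. Consistent when
#' instruments contributing at least half the weight are valid. The
#' standard error is the standard deviation of the statistic over
#' parametric resamples of the summary associations.
#'
#' @param h harmonized instruments (at least 3).
#' @param n_boot number of parametric bootstrap resamples (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  h <- .check_harmonized(h)
  J <- nrow(h)
  if (J < 3) stop("weighted median requires at least 3 instruments")
  point <- .weighted_median_theta(h$exposure_beta, h$outcome_beta, h$outcome_se)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    g <- stats::rnorm(J, h$exposure_beta, h$exposure_se)
    G <- stats::rnorm(J, h$outcome_beta, h$outcome_se)
    .weighted_median_theta(g, G, h$outcome_se)
  }, numeric(1))
  .mr_estimate("weighted_median", point, stats::sd(boots), J,
               effects_model = "bootstrap")
}

.weighted_median_theta <- function(g, G, se_G) {
  theta <- G / g
  w <- g^2 / se_G^2
  w <- w / sum(w)
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- cumsum(w) - w / 2
  stats::approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' MR-Egger regression
#'
#' Weighted (or, with an LD matrix, generalized) least-squares regression of
#' outcome on exposure associations with an intercept; a non-zero intercept
#' indicates directional pleiotropy. Because the fit is not invariant to
#' allele orientation, variant effects are first flipped so every exposure
#' association is positive.
#'
#' @param h harmonized instruments (at least 3).
#' @param ld optional [ld_matrix()]; when supplied the fit uses the
#'   correlated-instrument weighting matrix.
#' @param effects_model `"auto"`, `"fixed"` or `"random"`; random applies
#'   multiplicative inflation `max(1, sqrt(Q / (J - 2)))` to both standard
#'   errors.
#' @return An `mr_estimate` carrying slope and intercept with Q on `J - 2`
#'   degrees of freedom.
#' @export
mr_egger <- function(h, ld = NULL, effects_model = "auto") {
  h <- .check_harmonized(h)
  J <- nrow(h)
  if (J < 3) stop("MR-Egger requires at least 3 instruments")
  effects_model <- .resolve_effects_model(effects_model, J)
  flip <- ifelse(h$exposure_beta < 0, -1, 1)
  g <- flip * h$exposure_beta
  G <- flip * h$outcome_beta
  rho <- if (is.null(ld)) diag(J) else .align_ld(h, ld)
  rho <- rho * outer(flip, flip)
  oi <- .omega_inverse(h$outcome_se, rho)
  X <- cbind(intercept = 1, slope = g)
  xtoi <- crossprod(X, oi)
  cov_unscaled <- solve(xtoi %*% X)
  coefs <- drop(cov_unscaled %*% (xtoi %*% G))
  resid <- G - drop(X %*% coefs)
  Q <- drop(crossprod(resid, oi %*% resid))
  scale <- if (effects_model == "random") max(1, sqrt(Q / (J - 2))) else 1
  ses <- unname(sqrt(diag(cov_unscaled))) * scale
  .mr_estimate("egger", unname(coefs[2]), ses[2], J,
               q_statistic = Q, q_df = J - 2,
               egger_intercept = unname(coefs[1]), egger_intercept_se = ses[1],
               effects_model = effects_model)
}

#' Re-express an estimate per unit *reduction* in the exposure
#'
#' Negates the slope (and intercept) and mirrors the confidence interval so
#' effects read per 1-SD lowering of the exposure, the scale on which
#' lipid-lowering therapies are reported; p-values and heterogeneity are
#' unchanged. Applying the function twice restores the original estimate.
#'
#' @param e an `mr_estimate`.
#' @return The re-oriented `mr_estimate`.
#' @export
lowering_orientation <- function(e) {
  stopifnot(inherits(e, "mr_estimate"))
  new_or <- if (identical(e$orientation, "raising")) "lowering" else "raising"
  out <- e
  out$slope <- -e$slope
  out$ci_low <- -e$ci_high
  out$ci_high <- -e$ci_low
  if (!is.na(e$egger_intercept)) out$egger_intercept <- -e$egger_intercept
  out$orientation <- new_or
  out
}

#' Summarize an estimate as an odds ratio
#'
#' For binary outcomes the MR slope is a log odds ratio; this helper
#' exponentiates the slope and confidence bounds for reporting.
#'
#' @param e an `mr_estimate`.
#' @return Named list `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
odds_ratio <- function(e) {
  stopifnot(inherits(e, "mr_estimate"))
  list(or = exp(e$slope), ci_low = exp(e$ci_low), ci_high = exp(e$ci_high),
       p_value = e$p_value)
}

#' Tabulate MR estimates
#'
#' @param estimates a (possibly named) list of `mr_estimate` objects.
#' @return data.frame with one row per estimate.
#' @export
mr_table <- function(estimates) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  rows <- lapply(estimates, function(e) {
    data.frame(method = e$method, slope = e$slope, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, p_value = e$p_value,
               n_snps = e$n_snps, q_statistic = e$q_statistic,
               q_p_value = e$q_p_value, egger_intercept = e$egger_intercept,
               egger_intercept_p = e$egger_intercept_p,
               orientation = e$orientation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
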