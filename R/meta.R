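# Cross-study meta-analysis of MR estimates and subgroup comparison.

#' Meta-analyze MR estimates across studies
#'
#' Inverse-variance pooling across studies. Under the `auto` rule the model
#' is fixed-effects unless Cochran's Q suggests heterogeneity
#' (`q_p < het_alpha`), in which case a DerSimonian-Laird random-effects
#' model is used: `tau2 = max(0, (Q - (S-1)) / (sum(w) - sum(w^2)/sum(w)))`
#' with re-pooling weights `1 / (se^2 + tau2)`.
#'
#' @param estimates list of `mr_estimate` objects (at least 2) on the same
#'   scale and orientation.
#' @param rule `"auto"`, `"fixed"` or `"random"`.
#' @param het_alpha significance level on Q that triggers the switch to
#'   random effects (default 0.05).
#' @param study_labels optional character vector naming the studies.
#' @return Object of class `meta_result` with pooled slope/se, the model
#'   used, Q, its p-value and `tau2` (0 under fixed effects).
#' @export
meta_analyze <- function(estimates, rule = c("auto", "fixed", "random"),
                         het_alpha = 0.05, study_labels = NULL) {
  rule <- match.arg(rule)
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  S <- length(estimates)
  if (S < 2) stop("meta-analysis requires at least 2 estimates")
  stopifnot(all(vapply(estimates, inherits, logical(1), "mr_estimate")))
  orientations <- vapply(estimates, `[[`, character(1), "orientation")
  if (length(unique(orientations)) != 1) {
    stop("estimates mix raising and lowering orientations; align them first")
  }
  if (is.null(study_labels)) {
    study_labels <- names(estimates)
    if (is.null(study_labels)) study_labels <- paste0("study_", seq_len(S))
  }
  b <- vapply(estimates, `[[`, numeric(1), "slope")
  se <- vapply(estimates, `[[`, numeric(1), "se")
  w <- 1 / se^2
  pooled_fixed <- sum(w * b) / sum(w)
  Q <- sum(w * (b - pooled_fixed)^2)
  q_p <- stats::pchisq(Q, df = S - 1, lower.tail = FALSE)

  model <- switch(rule,
                  fixed = "fixed",
                  random = "random",
                  auto = if (q_p < het_alpha) "random" else "fixed")
  tau2 <- 0
  if (model == "random") {
    tau2 <- max(0, (Q - (S - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w_re <- 1 / (se^2 + tau2)
    pooled <- sum(w_re * b) / sum(w_re)
    pooled_se <- sqrt(1 / sum(w_re))
  } else {
    pooled <- pooled_fixed
    pooled_se <- sqrt(1 / sum(w))
  }
  z <- pooled / pooled_se
  structure(
    list(pooled_slope = pooled, pooled_se = pooled_se,
         ci_low = pooled - stats::qnorm(0.975) * pooled_se,
         ci_high = pooled + stats::qnorm(0.975) * pooled_se,
         p_value = 2 * stats::pnorm(-abs(z)),
         model = model, q_statistic = Q, q_p_value = q_p, tau2 = tau2,
         study_labels = study_labels, orientation = orientations[1],
         n_studies = S),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Meta-analysis (%s effects, %d studies, %s orientation)\n",
              x$model, x$n_studies, x$orientation))
  cat(sprintf("  pooled % .4g (se %.4g), 95%% CI [% .4g, % .4g], p = %.3g\n",
              x$pooled_slope, x$pooled_se, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  Q = %.4g (p = %.3g), tau2 = %.4g\n",
              x$q_statistic, x$q_p_value, x$tau2))
  invisible(x)
}

#' Two-sided z-test for a difference between two estimates
#'
#' Used to compare subgroup (for example sex- or ancestry-specific) MR
#' estimates: `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)` with a two-sided
#' normal p-value.
#'
#' @param a,b `mr_estimate` objects on the same scale and orientation.
#' @return Named list with `z` and `p`.
#' @export
subgroup_z_test <- function(a, b) {
  stopifnot(inherits(a, "mr_estimate"), inherits(b, "mr_estimate"))
  if (!identical(a$orientation, b$orientation)) {
    stop("estimates must share an orientation")
  }
  z <- (a$slope - b$slope) / sqrt(a$se^2 + b$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
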