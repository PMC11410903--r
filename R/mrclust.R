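# Clustering of variant-level causal estimates.
#
# Model: each Wald ratio theta_j (known standard error sigma_j) belongs to
# one of K substantive clusters (Normal(mu_k, sigma_j^2)), a null cluster
# (Normal(0, sigma_j^2)) or a junk cluster (Normal(theta_bar,
# sigma_j^2 + psi^2)), where theta_bar and psi^2 are the unweighted mean
# and variance of all ratios and stay fixed during fitting. The null and
# junk components demand substantial evidence of similarity before a
# substantive cluster forms, which guards against spurious clusters.

# One EM run for fixed K from given starting means; the iteration itself
# is compiled (src/em_fit.cpp).
.em_fit <- function(theta, sigma2, mu0, theta_bar, junk_var,
                    max_iter = 500, tol = 1e-8) {
  .em_fit_cpp(as.numeric(theta), as.numeric(sigma2), as.numeric(mu0),
              theta_bar, junk_var, as.integer(max_iter), tol)
}

#' Fit the clustered-MR mixture model
#'
#' Fits, by EM, mixtures with `K = 0 .. k_max` substantive clusters plus
#' the fixed null and junk components, selects K by BIC
#' (`-2 loglik + (2K + 1) log J`), and keeps the best of `n_restarts`
#' seeded restarts (initial means drawn from random quantiles of the
#' ratios) for each K. Observation variances `sigma_j^2` are treated as
#' known; the model accounts for differential uncertainty in the
#' variant-level estimates.
#'
#' @param ratios `ratio_estimates` from [wald_ratio()] (at least 5).
#' @param k_max largest number of substantive clusters tried (default 10).
#' @param n_restarts random restarts per K (default 20).
#' @param seed optional integer seed making restarts reproducible.
#' @param junk_scale_multiplier multiplies the junk component's dispersion
#'   anchor (default 1).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   falls below `tol` or after `max_iter` iterations.
#' @return Object of class `cluster_solution`: `k_substantive`, component
#'   `means`, mixing `proportions` (substantive clusters, then `null`,
#'   then `junk`), the per-variant `inclusion` probability matrix, `bic`,
#'   `loglik` and the per-iteration `loglik_trace` of the winning fit.
#' @export
fit_mixture <- function(ratios, k_max = 10, n_restarts = 20, seed = NULL,
                        junk_scale_multiplier = 1, max_iter = 500, tol = 1e-8) {
  stopifnot(is.data.frame(ratios),
            all(c("variant_id", "theta", "theta_se") %in% names(ratios)))
  J <- nrow(ratios)
  if (J < 5) stop("mixture clustering requires at least 5 ratio estimates")
  if (any(ratios$theta_se <= 0)) stop("theta_se must be positive")
  theta <- ratios$theta
  sigma2 <- ratios$theta_se^2
  theta_bar <- mean(theta)
  junk_var <- stats::var(theta) * junk_scale_multiplier^2
  if (!is.finite(junk_var) || junk_var <= 0) junk_var <- 1

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (K in 0:k_max) {
    n_try <- if (K == 0) 1 else n_restarts
    for (rep in seq_len(n_try)) {
      mu0 <- if (K == 0) numeric(0) else
        unname(stats::quantile(theta, sort(stats::runif(K))))
      fit <- .em_fit(theta, sigma2, mu0, theta_bar, junk_var, max_iter, tol)
      k_eff <- fit$k
      bic <- -2 * fit$loglik + (2 * k_eff + 1) * log(J)
      if (is.null(best) || bic < best$bic - 1e-12) {
        best <- fit
        best$bic <- bic
      }
    }
  }

  comp_names <- c(if (best$k > 0) paste0("cluster_", seq_len(best$k)),
                  "null", "junk")
  colnames(best$inclusion) <- comp_names
  rownames(best$inclusion) <- ratios$variant_id
  structure(
    list(k_substantive = best$k,
         means = if (best$k > 0) stats::setNames(best$mu, comp_names[seq_len(best$k)])
                 else stats::setNames(numeric(0), character(0)),
         proportions = stats::setNames(best$pi, comp_names),
         junk_scale = sqrt(junk_var),
         junk_center = theta_bar,
         inclusion = best$inclusion,
         bic = best$bic,
         loglik = best$loglik,
         loglik_trace = best$loglik_trace,
         seed = seed),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Clustered MR solution: %d substantive cluster(s), J = %d\n",
              x$k_substantive, nrow(x$inclusion)))
  if (x$k_substantive > 0) {
    cat("  means:", paste(signif(x$means, 4), collapse = ", "), "\n")
  }
  cat("  proportions:",
      paste(sprintf("%s %.2f", names(x$proportions), x$proportions),
            collapse = ", "), "\n")
  cat(sprintf("  loglik %.4g, BIC %.4g\n", x$loglik, x$bic))
  invisible(x)
}

#' Report clusters passing the inclusion and size rules
#'
#' A variant is a member of a substantive cluster when that cluster is its
#' maximum-probability component and its inclusion probability strictly
#' exceeds `min_inclusion`; a cluster is reported only when at least
#' `min_size` variants qualify. For each reported cluster the IVW,
#' weighted-median and MR-Egger estimates are recomputed on the member
#' instruments (uncorrelated formulas; genome-wide instruments are assumed
#' already pruned to independence).
#'
#' @param sol a `cluster_solution`.
#' @param instruments harmonized instruments covering the clustered
#'   variants (matched by `variant_id`); may be `NULL` when
#'   `with_estimates = FALSE`.
#' @param min_inclusion inclusion-probability threshold, strict (default 0.80).
#' @param min_size minimum qualifying members (default 4).
#' @param with_estimates recompute per-cluster MR estimates (default `TRUE`);
#'   set `FALSE` when only cluster membership is needed (e.g. calibration
#'   runs).
#' @param n_boot,seed bootstrap controls passed to [mr_weighted_median()].
#' @return List of `reported_cluster` objects (possibly empty), each with
#'   `cluster_id`, `member_variant_ids`, `mean` and an `estimates` list
#'   (`ivw`, `weighted_median`, `egger`).
#' @export
report_clusters <- function(sol, instruments = NULL, min_inclusion = 0.80,
                            min_size = 4, with_estimates = TRUE,
                            n_boot = 1000, seed = NULL) {
  stopifnot(inherits(sol, "cluster_solution"))
  if (sol$k_substantive == 0) return(list())
  if (with_estimates) instruments <- .check_harmonized(instruments)
  argmax <- max.col(sol$inclusion, ties.method = "first")
  out <- list()
  for (k in seq_len(sol$k_substantive)) {
    qualify <- which(argmax == k & sol$inclusion[, k] > min_inclusion)
    if (length(qualify) < min_size) next
    ids <- rownames(sol$inclusion)[qualify]
    ests <- NULL
    if (with_estimates) {
      sub <- instruments[match(ids, instruments$variant_id), , drop = FALSE]
      if (anyNA(sub$variant_id)) {
        stop("instruments missing for cluster member(s): ",
             paste(setdiff(ids, instruments$variant_id), collapse = ", "))
      }
      ests <- list(
        ivw = mr_ivw(sub),
        weighted_median = mr_weighted_median(sub, n_boot = n_boot, seed = seed),
        egger = mr_egger(sub)
      )
    }
    out[[names(sol$means)[k]]] <- structure(
      list(cluster_id = names(sol$means)[k],
           member_variant_ids = ids,
           mean = unname(sol$means[k]),
           estimates = ests),
      class = "reported_cluster"
    )
  }
  out
}

#' @export
print.reported_cluster <- function(x, ...) {
  cat(sprintf("%s: %d members, mean % .4g\n", x$cluster_id,
              length(x$member_variant_ids), x$mean))
  if (!is.null(x$estimates)) {
    cat(sprintf("  ivw % .4g (p %.3g)\n", x$estimates$ivw$slope,
                x$estimates$ivw$p_value))
  }
  invisible(x)
}
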