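# Approximate-Bayes-factor colocalization of two traits in a gene region.
#
# Hypotheses: H0 no association with either trait; H1/H2 association with
# one trait only; H3 two distinct causal variants, one per trait; H4 one
# shared causal variant. Posteriors follow from per-variant Wakefield
# approximate Bayes factors combined with per-variant priors.

#' Colocalization configuration
#'
#' Per-variant prior probabilities and effect-size prior standard
#' deviations. Defaults follow the standard recommendation: 1e-4 for a
#' variant associated with trait 1 only, 1e-4 for trait 2 only, 1e-5 for a
#' shared variant; prior effect SDs 0.15 (quantitative traits, SD units)
#' and 0.2 (binary traits, log-odds units).
#'
#' @param p1,p2,p12 prior probabilities; must satisfy `p1 + p2 + p12 < 1`.
#' @param prior_sd_quant,prior_sd_binary prior SD of a true effect for
#'   quantitative and binary traits.
#' @param maf_min variants with minor allele frequency at or below this are
#'   excluded (default 0.001, i.e. MAF > 0.1%).
#' @return Object of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd_quant = 0.15, prior_sd_binary = 0.2,
                         maf_min = 0.001) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1,
            prior_sd_quant > 0, prior_sd_binary > 0,
            maf_min >= 0, maf_min < 0.5)
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_sd_quant = prior_sd_quant,
                 prior_sd_binary = prior_sd_binary,
                 maf_min = maf_min),
            class = "coloc_config")
}

#' Log approximate Bayes factor for one association
#'
#' Wakefield's approximation: with `V = se^2`, `W = prior_sd^2`,
#' `z = beta/se` and `r = W / (V + W)`, the log Bayes factor in favour of a
#' non-zero effect is `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se association estimate and its standard error (vectorized).
#' @param prior_sd prior standard deviation of a true effect.
#' @return Log approximate Bayes factor(s).
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive")
  if (prior_sd < 0) stop("prior_sd must be non-negative")
  V <- se^2
  r <- prior_sd^2 / (V + prior_sd^2)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.prior_sd_for <- function(ds, cfg) {
  if (ds$trait_type == "binary") cfg$prior_sd_binary else cfg$prior_sd_quant
}

#' Bayesian colocalization of two traits in a region
#'
#' Restricts both datasets to the flanked gene region, applies the minor
#' allele frequency filter, intersects the variant lists and computes the
#' posterior probabilities of hypotheses H0-H4 from per-variant approximate
#' Bayes factors, all in log space. Also reports the conditional
#' probability of a shared variant given any trait-2 association
#' (`PP4 / (PP3 + PP4)`), the per-variant shared-signal posteriors, and the
#' lead (maximum posterior) variant.
#'
#' @param trait1,trait2 `summary_dataset` objects.
#' @param region [gene_region()]; the tested window is the gene plus flank.
#' @param cfg [coloc_config()].
#' @return Object of class `coloc_result`.
#' @export
colocalize <- function(trait1, trait2, region, cfg = coloc_config()) {
  stopifnot(inherits(trait1, "summary_dataset"),
            inherits(trait2, "summary_dataset"),
            inherits(region, "gene_region"),
            inherits(cfg, "coloc_config"))
  lo <- region$start - region$flank
  hi <- region$end + region$flank
  take <- function(ds) {
    r <- ds$records
    r <- r[r$chromosome == region$chromosome & r$position >= lo &
             r$position <= hi, , drop = FALSE]
    maf_ok <- is.na(r$eaf) | pmin(r$eaf, 1 - r$eaf) > cfg$maf_min
    r[maf_ok, , drop = FALSE]
  }
  r1 <- take(trait1)
  r2 <- take(trait2)
  ids <- intersect(r1$variant_id, r2$variant_id)
  if (length(ids) == 0) {
    stop("no shared variants in region ", region$gene_name,
         " after the MAF filter")
  }
  r1 <- r1[match(ids, r1$variant_id), ]
  r2 <- r2[match(ids, r2$variant_id), ]
  J <- length(ids)

  lbf1 <- log_abf(r1$beta, r1$se, .prior_sd_for(trait1, cfg))
  lbf2 <- log_abf(r2$beta, r2$se, .prior_sd_for(trait2, cfg))

  s1 <- .logsumexp(lbf1)
  s2 <- .logsumexp(lbf2)
  s12 <- .logsumexp(lbf1 + lbf2)
  # H3 sums over ordered pairs of distinct variants:
  # log(exp(s1 + s2) - exp(s12)), computed in log space.
  gap <- s12 - (s1 + s2)
  if (J == 1 || gap >= 0) {
    if (J > 1) message("colocalize: H3 mass numerically zero; PP3 set to 0")
    s3 <- -Inf
  } else {
    s3 <- s1 + s2 + log1p(-exp(gap))
  }

  logpost <- c(
    h0 = 0,
    h1 = log(cfg$p1) + s1,
    h2 = log(cfg$p2) + s2,
    h3 = log(cfg$p1) + log(cfg$p2) + s3,
    h4 = log(cfg$p12) + s12
  )
  pp <- exp(logpost - .logsumexp(logpost))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)

  pv <- exp(lbf1 + lbf2 - s12)
  pv <- pv / sum(pv)
  names(pv) <- ids

  denom <- pp[["PP3"]] + pp[["PP4"]]
  structure(
    list(pp = pp,
         conditional_pp4 = if (denom > 0) pp[["PP4"]] / denom else NA_real_,
         per_variant_h4 = pv,
         lead_variant = ids[which.max(pv)],
         n_variants_tested = J,
         region = region$gene_name,
         priors = c(p1 = cfg$p1, p2 = cfg$p2, p12 = cfg$p12)),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization:", x$region, sprintf("(%d variants)\n", x$n_variants_tested))
  cat("  ", paste(sprintf("%s = %.3f", names(x$pp), x$pp), collapse = ", "), "\n")
  cat(sprintf("  conditional PP4 = %.3f, lead variant %s (posterior %.3f)\n",
              x$conditional_pp4, x$lead_variant,
              x$per_variant_h4[[x$lead_variant]]))
  invisible(x)
}

#' Conditional probability of colocalization
#'
#' The posterior probability of a shared causal variant conditional on the
#' presence of a variant associated with the second trait:
#' `PP4 / (PP3 + PP4)`. Useful when power to detect the trait-2 association
#' is limited.
#'
#' @param res a `coloc_result`.
#' @return A fraction, or `NA` when `PP3 + PP4` is zero.
#' @export
conditional_probability <- function(res) {
  stopifnot(inherits(res, "coloc_result"))
  denom <- res$pp[["PP3"]] + res$pp[["PP4"]]
  if (denom <= 0) return(NA_real_)
  unname(res$pp[["PP4"]] / denom)
}
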