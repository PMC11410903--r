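# Synthetic GWAS summary statistics with known truth.
#
# Standardized-genotype parameterization: observed effects carry sampling
# standard error 1/sqrt(n) for quantitative traits and
# 1/sqrt(n * phi * (1 - phi)) on the log-odds scale for binary traits with
# case fraction phi. This deliberately omits allele-frequency-dependent
# precision and logistic fine structure; it reproduces the statistical
# geometry the estimators consume (effect/se pairs with known truth).

.gw_z <- function(p_max = 5e-8) stats::qnorm(1 - p_max / 2)

#' Configuration for the genome-wide generator
#'
#' Defaults emulate the structure of a genome-wide LDL-cholesterol
#' instrument set taken to a large biobank gallstone GWAS: exposure sample
#' size of the European-ancestry lipids meta-analysis (1,231,289), outcome
#' sample size of a 367,289-person biobank with case fraction 0.0832
#' (30,547 cases), two substantive clusters with opposing slopes (-0.3 and
#' +0.4) plus null (0.15) and junk (0.05) weight.
#'
#' @param n_variants number of variants simulated.
#' @param cluster_slopes true substantive cluster slopes (log-odds per SD
#'   of exposure).
#' @param cluster_weights probabilities over components in the order
#'   `c(substantive..., null, junk)`; must sum to 1.
#' @param exposure_n,outcome_n GWAS sample sizes.
#' @param outcome_case_fraction case fraction of the binary outcome.
#' @param exposure_effect_sd SD of true variant-exposure effects before the
#'   significance conditioning.
#' @param junk_pleiotropy_sd SD of direct (pleiotropic) outcome effects for
#'   junk variants.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return Object of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_variants = 100,
                              cluster_slopes = c(-0.3, 0.4),
                              cluster_weights = c(0.4, 0.4, 0.15, 0.05),
                              exposure_n = 1231289,
                              outcome_n = 367289,
                              outcome_case_fraction = 30547 / 367289,
                              exposure_effect_sd = 0.02,
                              junk_pleiotropy_sd = 0.05,
                              seed = 1) {
  k <- length(cluster_slopes)
  if (length(cluster_weights) != k + 2) {
    stop("cluster_weights must have length(cluster_slopes) + 2 entries ",
         "(substantive..., null, junk)")
  }
  if (abs(sum(cluster_weights) - 1) > 1e-8) stop("cluster_weights must sum to 1")
  stopifnot(n_variants >= 1, exposure_n > 0, outcome_n > 0,
            outcome_case_fraction > 0, outcome_case_fraction < 1,
            exposure_effect_sd > 0, junk_pleiotropy_sd >= 0)
  structure(as.list(environment())[c("n_variants", "cluster_slopes",
                                     "cluster_weights", "exposure_n",
                                     "outcome_n", "outcome_case_fraction",
                                     "exposure_effect_sd",
                                     "junk_pleiotropy_sd", "seed")],
            class = "genome_sim_config")
}

# Draw true exposure effects conditioned to reach genome-wide significance,
# by batched rejection sampling with a hard cap on attempts.
.draw_significant_gamma <- function(J, sd, threshold, cap = 10000L * J) {
  out <- numeric(0)
  attempts <- 0L
  while (length(out) < J) {
    batch <- max(J, 1000L)
    attempts <- attempts + batch
    if (attempts > cap) {
      stop("rejection sampling failed to reach genome-wide significance; ",
           "increase exposure_effect_sd")
    }
    draw <- stats::rnorm(batch, 0, sd)
    out <- c(out, draw[abs(draw) > threshold])
  }
  out[seq_len(J)]
}

.variant_frame <- function(ids, chr, pos, eaf, beta, se, n) {
  data.frame(variant_id = ids, chromosome = chr, position = pos,
             effect_allele = "A", other_allele = "G",
             eaf = eaf, beta = beta, se = se,
             p_value = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
             n = n, stringsAsFactors = FALSE)
}

#' Simulate genome-wide exposure and outcome summary statistics
#'
#' Per variant: a true exposure effect is drawn from
#' `Normal(0, exposure_effect_sd^2)` conditioned (by rejection) to reach
#' genome-wide significance at the exposure sample size; a component label
#' is drawn by `cluster_weights`; the true outcome effect is the cluster
#' slope times the exposure effect (substantive), zero (null) or a direct
#' pleiotropic draw (junk). Observed effects add independent Gaussian
#' sampling noise at the nominal standard errors. Variants are simulated
#' without LD (spread across chromosomes).
#'
#' @param cfg a [genome_sim_config()].
#' @return List with `exposure` and `outcome` [summary_dataset()]s and a
#'   `truth` data.frame (`variant_id`, `component`, `true_gamma`,
#'   `true_Gamma`, `true_slope`).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  set.seed(cfg$seed)
  J <- cfg$n_variants
  se_g <- 1 / sqrt(cfg$exposure_n)
  phi <- cfg$outcome_case_fraction
  se_G <- 1 / sqrt(cfg$outcome_n * phi * (1 - phi))

  gamma <- .draw_significant_gamma(J, cfg$exposure_effect_sd, .gw_z() * se_g)
  k <- length(cfg$cluster_slopes)
  components <- c(if (k > 0) paste0("cluster_", seq_len(k)), "null", "junk")
  label <- sample(components, J, replace = TRUE, prob = cfg$cluster_weights)
  slope_of <- stats::setNames(c(cfg$cluster_slopes, 0, NA_real_), components)
  Gamma <- ifelse(label == "junk",
                  stats::rnorm(J, 0, cfg$junk_pleiotropy_sd),
                  slope_of[label] * gamma)

  gamma_hat <- gamma + stats::rnorm(J, 0, se_g)
  Gamma_hat <- Gamma + stats::rnorm(J, 0, se_G)

  ids <- sprintf("rs%06d", seq_len(J))
  chr <- as.character(rep_len(1:22, J))
  pos <- 1e5 * seq_len(J)
  eaf <- stats::runif(J, 0.05, 0.95)

  exposure <- summary_dataset(
    .variant_frame(ids, chr, pos, eaf, gamma_hat, se_g, cfg$exposure_n),
    trait_name = "exposure", trait_type = "quantitative")
  outcome <- summary_dataset(
    .variant_frame(ids, chr, pos, eaf, Gamma_hat, se_G, cfg$outcome_n),
    trait_name = "outcome", trait_type = "binary", case_fraction = phi)
  truth <- data.frame(variant_id = ids, component = label,
                      true_gamma = gamma, true_Gamma = Gamma,
                      true_slope = unname(slope_of[label]),
                      stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Configuration for the regional (colocalization) generator
#'
#' Defaults match a dense cis region tested for colocalization: 200
#' variants in an AR(1) LD block (rho = 0.9), causal effect 0.05 per SD,
#' and 50,000 individuals per trait.
#'
#' @param n_variants variants in the region.
#' @param ld_rho AR(1) autocorrelation of adjacent variants, |rho| < 1.
#' @param causal_mode `"shared"` (one causal variant for both traits),
#'   `"distinct"` (one per trait, far apart in the block),
#'   `"trait1_only"`, or `"none"`.
#' @param causal_betas causal effect size(s), recycled over traits.
#' @param n1,n2 per-trait sample sizes.
#' @param seed integer seed.
#' @return Object of class `region_sim_config`.
#' @export
region_sim_config <- function(n_variants = 200, ld_rho = 0.9,
                              causal_mode = c("shared", "distinct",
                                              "trait1_only", "none"),
                              causal_betas = 0.05,
                              n1 = 50000, n2 = 50000, seed = 1) {
  causal_mode <- match.arg(causal_mode)
  stopifnot(abs(ld_rho) < 1, n_variants >= 2, n1 > 0, n2 > 0)
  structure(list(n_variants = n_variants, ld_rho = ld_rho,
                 causal_mode = causal_mode, causal_betas = causal_betas,
                 n1 = n1, n2 = n2, seed = seed),
            class = "region_sim_config")
}

#' Simulate a two-trait region with AR(1) LD
#'
#' Builds `R[i, j] = rho^|i - j|`, places causal effects according to
#' `causal_mode` (shared: mid-block index for both traits; distinct:
#' quarter- and three-quarter-block indices), draws each trait's z-scores
#' from `MVN(sqrt(n) R b, R)`, and returns summary datasets with
#' `beta = z / sqrt(n)` and `se = 1 / sqrt(n)` plus the LD matrix and the
#' causal truth.
#'
#' @param cfg a [region_sim_config()].
#' @return List with `trait1`, `trait2` ([summary_dataset()]s), `ld`
#'   ([ld_matrix()]), `region` ([gene_region()] spanning the block) and
#'   `truth` (causal indices/ids per trait).
#' @export
simulate_region <- function(cfg) {
  stopifnot(inherits(cfg, "region_sim_config"))
  set.seed(cfg$seed)
  J <- cfg$n_variants
  R <- cfg$ld_rho^abs(outer(seq_len(J), seq_len(J), "-"))
  ids <- sprintf("rs%06d", seq_len(J))

  causal1 <- causal2 <- integer(0)
  if (cfg$causal_mode == "shared") {
    causal1 <- causal2 <- max(1L, round(J / 2))
  } else if (cfg$causal_mode == "distinct") {
    causal1 <- max(1L, round(J / 4))
    causal2 <- min(J, round(3 * J / 4))
  } else if (cfg$causal_mode == "trait1_only") {
    causal1 <- max(1L, round(J / 2))
  }
  if (any(c(causal1, causal2) > J)) stop("causal index out of range")
  betas <- rep_len(cfg$causal_betas, 2)

  L <- chol(R)  # upper triangular, R = t(L) %*% L
  draw_trait <- function(causal, b_size, n) {
    b <- numeric(J)
    b[causal] <- b_size
    mu <- sqrt(n) * drop(R %*% b)
    z <- mu + drop(t(L) %*% stats::rnorm(J))
    z
  }
  z1 <- draw_trait(causal1, betas[1], cfg$n1)
  z2 <- draw_trait(causal2, betas[2], cfg$n2)

  eaf <- stats::runif(J, 0.05, 0.95)
  pos <- 1000 * seq_len(J)
  t1 <- summary_dataset(
    .variant_frame(ids, "1", pos, eaf, z1 / sqrt(cfg$n1), 1 / sqrt(cfg$n1), cfg$n1),
    trait_name = "trait1", trait_type = "quantitative")
  t2 <- summary_dataset(
    .variant_frame(ids, "1", pos, eaf, z2 / sqrt(cfg$n2), 1 / sqrt(cfg$n2), cfg$n2),
    trait_name = "trait2", trait_type = "quantitative")
  list(trait1 = t1, trait2 = t2,
       ld = ld_matrix(R, ids),
       region = gene_region("sim_region", "1", min(pos), max(pos), flank = 0),
       truth = list(causal_mode = cfg$causal_mode,
                    causal1 = ids[causal1], causal2 = ids[causal2],
                    causal_betas = betas))
}

#' Simulate several studies of the same exposure-outcome pair
#'
#' With `shared_truth = TRUE` the true variant effects are generated once
#' (from the first configuration) and every study observes them with its
#' own sampling noise and sample sizes — the fixed-effects regime for
#' meta-analysis. Otherwise each study draws its own truth.
#'
#' @param cfgs list of at least two [genome_sim_config()]s.
#' @param shared_truth logical (default `TRUE`).
#' @param seed integer seed controlling study-level noise.
#' @return List of per-study lists as returned by [simulate_genome()].
#' @export
simulate_multistudy <- function(cfgs, shared_truth = TRUE, seed = 1) {
  if (!is.list(cfgs) || length(cfgs) < 2 ||
      !all(vapply(cfgs, inherits, logical(1), "genome_sim_config"))) {
    stop("cfgs must be a list of at least two genome_sim_config objects")
  }
  if (!shared_truth) {
    return(lapply(seq_along(cfgs), function(s) {
      cfg <- cfgs[[s]]
      cfg$seed <- seed + s
      simulate_genome(cfg)
    }))
  }
  base_cfg <- cfgs[[1]]
  base_cfg$seed <- seed
  base <- simulate_genome(base_cfg)
  truth <- base$truth
  J <- nrow(truth)
  lapply(seq_along(cfgs), function(s) {
    cfg <- cfgs[[s]]
    if (cfg$n_variants != J) stop("all configs must share n_variants under shared truth")
    set.seed(seed + 1000L * s)
    se_g <- 1 / sqrt(cfg$exposure_n)
    phi <- cfg$outcome_case_fraction
    se_G <- 1 / sqrt(cfg$outcome_n * phi * (1 - phi))
    gamma_hat <- truth$true_gamma + stats::rnorm(J, 0, se_g)
    Gamma_hat <- truth$true_Gamma + stats::rnorm(J, 0, se_G)
    ex0 <- base$exposure$records
    exposure <- summary_dataset(
      .variant_frame(ex0$variant_id, ex0$chromosome, ex0$position, ex0$eaf,
                     gamma_hat, se_g, cfg$exposure_n),
      trait_name = "exposure", trait_type = "quantitative")
    outcome <- summary_dataset(
      .variant_frame(ex0$variant_id, ex0$chromosome, ex0$position, ex0$eaf,
                     Gamma_hat, se_G, cfg$outcome_n),
      trait_name = "outcome", trait_type = "binary", case_fraction = phi)
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}
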