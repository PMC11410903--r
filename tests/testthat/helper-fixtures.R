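# Shared fixture builders: small in-code datasets used across test files.

# Harmonized-instrument table straight from effect vectors.
make_harmonized <- function(g, G, se_G, se_g = rep(1e-6, length(g)),
                            ids = sprintf("v%03d", seq_along(g))) {
  out <- data.frame(
    variant_id = ids,
    exposure_beta = g, exposure_se = se_g,
    outcome_beta = G, outcome_se = se_G,
    effect_allele = "A", other_allele = "G",
    eaf_exposure = 0.3, eaf_outcome = 0.3,
    proxy_of = NA_character_, harmonization_action = "kept",
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_instruments", "data.frame")
  out
}

# Variant-record data.frame for summary_dataset().
make_records <- function(ids, beta, se, p = NULL, chr = "1",
                         pos = seq_along(ids) * 1000, ea = "A", oa = "G",
                         eaf = 0.3, n = 10000) {
  if (is.null(p)) p <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(variant_id = ids, chromosome = chr, position = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, p_value = p, n = n,
             stringsAsFactors = FALSE)
}

make_dataset <- function(..., trait_name = "trait",
                         trait_type = "quantitative", case_fraction = NULL) {
  summary_dataset(make_records(...), trait_name, trait_type, case_fraction)
}

# A one-variant mr_estimate with exactly the requested slope and se.
make_estimate <- function(slope, se) {
  mr_ivw(make_harmonized(g = 1, G = slope, se_G = se), effects_model = "fixed")
}

# Ratio estimates for clustering tests.
make_ratios <- function(theta, theta_se) {
  out <- data.frame(variant_id = sprintf("v%03d", seq_along(theta)),
                    theta = theta, theta_se = theta_se,
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_estimates", "data.frame")
  out
}
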