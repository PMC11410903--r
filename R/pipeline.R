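# End-to-end orchestration of the two analysis tracks plus cohort
# bookkeeping. Slopes are estimated on the raising orientation internally
# and re-expressed per 1-SD exposure *reduction* (with odds ratios for
# binary outcomes) at the report layer.

#' Drug-target MR with colocalization for one gene region
#'
#' Selects cis instruments (low-LD pruning, `r^2 < 0.1` by default),
#' harmonizes them against the outcome, computes the correlated-instrument
#' IVW, MR-Egger and weighted-median estimates in the lowering orientation,
#' and runs colocalization over the same region. Targets without a single
#' significant variant produce a `not_instrumentable` report rather than an
#' error.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param ld [ld_matrix()] covering the region.
#' @param region [gene_region()] for the drug-target gene.
#' @param p_max,r2_max selection thresholds (defaults 5e-8 and 0.1).
#' @param proxy_r2_min proxy threshold for [harmonize()].
#' @param coloc_cfg [coloc_config()].
#' @param n_boot,seed weighted-median bootstrap controls.
#' @return List of class `drug_target_report`.
#' @export
run_drug_target <- function(exposure, outcome, ld, region,
                            p_max = 5e-8, r2_max = 0.1, proxy_r2_min = 0.8,
                            coloc_cfg = coloc_config(), n_boot = 1000,
                            seed = NULL) {
  instruments <- select_cis_instruments(exposure, region, ld,
                                        p_max = p_max, r2_max = r2_max)
  report <- list(target = region$gene_name,
                 thresholds = list(p_max = p_max, r2_max = r2_max,
                                   flank = region$flank,
                                   proxy_r2_min = proxy_r2_min),
                 n_instruments = length(instruments$variant_ids),
                 instruments = instruments)
  if (length(instruments$variant_ids) == 0) {
    report$status <- "not_instrumentable"
    class(report) <- "drug_target_report"
    return(report)
  }
  ex_sub <- exposure
  ex_sub$records <- exposure$records[
    match(instruments$variant_ids, exposure$records$variant_id), , drop = FALSE]
  harm <- harmonize(ex_sub, outcome, ld = ld, proxy_r2_min = proxy_r2_min)
  kept <- retained(harm)
  if (nrow(kept) == 0) {
    report$status <- "no_harmonizable_instruments"
    class(report) <- "drug_target_report"
    return(report)
  }
  estimates <- list(ivw = mr_ivw_correlated(kept, ld))
  if (nrow(kept) >= 3) {
    estimates$egger <- mr_egger(kept, ld = ld)
    estimates$weighted_median <- mr_weighted_median(kept, n_boot = n_boot,
                                                    seed = seed)
  }
  estimates <- lapply(estimates, lowering_orientation)
  report$status <- "ok"
  report$harmonization <- table(harm$harmonization_action)
  report$estimates <- estimates
  report$mr_table <- mr_table(estimates)
  if (outcome$trait_type == "binary") {
    report$odds_ratios <- lapply(estimates, odds_ratio)
  }
  report$coloc <- colocalize(exposure, outcome, region, coloc_cfg)
  class(report) <- "drug_target_report"
  report
}

#' @export
print.drug_target_report <- function(x, ...) {
  cat("Drug-target MR report:", x$target, "-", x$status, "\n")
  cat("  instruments:", x$n_instruments, "\n")
  if (identical(x$status, "ok")) {
    print(x$mr_table)
    cat(sprintf("  coloc PP4 = %.3f (conditional %.3f)\n",
                x$coloc$pp[["PP4"]], x$coloc$conditional_pp4))
  }
  invisible(x)
}

#' Genome-wide clustered MR
#'
#' Selects independent genome-wide instruments (`r^2 < 0.001`), harmonizes
#' them, computes all-variant IVW/weighted-median/MR-Egger estimates,
#' clusters the variant-level Wald ratios with [fit_mixture()], reports
#' clusters passing the inclusion-probability and size rules with
#' per-cluster estimates, and repeats the all-variant analysis with a
#' user-supplied exclusion list as a sensitivity analysis.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param ld optional [ld_matrix()] (omit for pre-pruned/independent data).
#' @param exclusions character vector of variant ids for the sensitivity
#'   re-run (e.g. variants linked to candidate confounders).
#' @param p_max,r2_max selection thresholds (defaults 5e-8 and 0.001).
#' @param k_max,n_restarts,min_inclusion,min_size clustering controls, see
#'   [fit_mixture()] and [report_clusters()].
#' @param n_boot,seed stochastic-step controls.
#' @return List of class `clustered_report`.
#' @export
run_clustered <- function(exposure, outcome, ld = NULL, exclusions = character(0),
                          p_max = 5e-8, r2_max = 0.001,
                          k_max = 10, n_restarts = 20,
                          min_inclusion = 0.80, min_size = 4,
                          n_boot = 1000, seed = 1) {
  instruments <- select_genomewide_instruments(exposure, ld,
                                               p_max = p_max, r2_max = r2_max)
  if (length(instruments$variant_ids) == 0) {
    stop("no genome-wide significant instruments")
  }
  ex_sub <- exposure
  ex_sub$records <- exposure$records[
    match(instruments$variant_ids, exposure$records$variant_id), , drop = FALSE]
  harm <- harmonize(ex_sub, outcome, ld = ld)
  kept <- retained(harm)
  all_estimates <- list(ivw = mr_ivw(kept))
  if (nrow(kept) >= 3) {
    all_estimates$egger <- mr_egger(kept)
    all_estimates$weighted_median <- mr_weighted_median(kept, n_boot = n_boot,
                                                        seed = seed)
  }
  all_estimates <- lapply(all_estimates, lowering_orientation)
  ratios <- wald_ratio(kept)
  sol <- fit_mixture(ratios, k_max = k_max, n_restarts = n_restarts, seed = seed)
  clusters <- report_clusters(sol, kept, min_inclusion = min_inclusion,
                              min_size = min_size, n_boot = n_boot, seed = seed)
  clusters <- lapply(clusters, function(cl) {
    cl$estimates <- lapply(cl$estimates, lowering_orientation)
    cl
  })

  sensitivity <- NULL
  if (length(exclusions) > 0) {
    sens_kept <- kept[!(kept$variant_id %in% exclusions), , drop = FALSE]
    sens <- list(ivw = mr_ivw(sens_kept))
    if (nrow(sens_kept) >= 3) {
      sens$egger <- mr_egger(sens_kept)
      sens$weighted_median <- mr_weighted_median(sens_kept, n_boot = n_boot,
                                                 seed = seed)
    }
    sensitivity <- list(excluded = intersect(exclusions, kept$variant_id),
                        n_snps = nrow(sens_kept),
                        estimates = lapply(sens, lowering_orientation))
  }

  structure(
    list(thresholds = list(p_max = p_max, r2_max = r2_max,
                           min_inclusion = min_inclusion, min_size = min_size),
         n_instruments = length(instruments$variant_ids),
         n_retained = nrow(kept),
         harmonization = table(harm$harmonization_action),
         all_snp_estimates = all_estimates,
         all_snp_table = mr_table(all_estimates),
         ratios = ratios,
         solution = sol,
         clusters = clusters,
         sensitivity = sensitivity,
         seed = seed),
    class = "clustered_report"
  )
}

#' @export
print.clustered_report <- function(x, ...) {
  cat("Clustered MR report\n")
  cat(sprintf("  instruments: %d selected, %d retained\n",
              x$n_instruments, x$n_retained))
  print(x$all_snp_table)
  cat(sprintf("  substantive clusters fitted: %d, reported: %d\n",
              x$solution$k_substantive, length(x$clusters)))
  invisible(x)
}

#' Cohort summary percentages and totals
#'
#' Turns labeled cohort counts into the percentages displayed in baseline
#' tables (rounded to one decimal) and computes grand totals: per-study
#' totals, total individuals and total cases across studies.
#'
#' @param counts data.frame with columns `study`, `group` (e.g. `cases` /
#'   `controls`), `variable`, `level`, `count` (non-negative integers).
#' @param group_sizes data.frame with columns `study`, `group`, `n`, the
#'   denominator for each study-group.
#' @return List of class `cohort_summary`: `table` (the counts with a
#'   `percent` column), `study_totals`, `total_individuals`, `total_cases`.
#'   Percentages with a zero denominator are reported missing.
#' @export
cohort_summary <- function(counts, group_sizes) {
  need <- c("study", "group", "variable", "level", "count")
  stopifnot(all(need %in% names(counts)),
            all(c("study", "group", "n") %in% names(group_sizes)))
  if (any(counts$count < 0) || any(group_sizes$n < 0)) {
    stop("counts must be non-negative")
  }
  key <- paste(counts$study, counts$group)
  gkey <- paste(group_sizes$study, group_sizes$group)
  if (anyDuplicated(gkey)) stop("duplicate study/group rows in group_sizes")
  denom <- group_sizes$n[match(key, gkey)]
  if (anyNA(denom)) {
    stop("group_sizes missing for: ",
         paste(unique(key[is.na(denom)]), collapse = ", "))
  }
  out <- counts
  out$percent <- ifelse(denom > 0, round(100 * counts$count / denom, 1), NA_real_)

  # level counts must not exceed their group denominator
  agg <- stats::aggregate(count ~ study + group + variable, data = counts, sum)
  adenom <- group_sizes$n[match(paste(agg$study, agg$group), gkey)]
  if (any(agg$count > adenom)) {
    stop("level counts exceed the group total for at least one variable")
  }

  study_totals <- stats::aggregate(n ~ study, data = group_sizes, sum)
  structure(
    list(table = out,
         study_totals = study_totals,
         total_individuals = sum(group_sizes$n),
         total_cases = sum(group_sizes$n[group_sizes$group == "cases"])),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  print(x$table)
  cat(sprintf("total individuals %d; total cases %d\n",
              x$total_individuals, x$total_cases))
  invisible(x)
}

# Strip classes/tables so a report serializes cleanly to JSON.
.jsonable <- function(x) {
  if (inherits(x, "table")) return(as.list(x))
  if (inherits(x, "ld_matrix")) return(NULL)
  if (is.list(x)) {
    out <- lapply(unclass(x), .jsonable)
    return(out[!vapply(out, is.null, logical(1))])
  }
  x
}

#' Write an analysis report as JSON
#'
#' Serializes a report (drug-target, clustered, meta or coloc result) with
#' full numeric precision under a versioned schema tag.
#'
#' @param report any of the package's report/result objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(schema = "targetmr-report/1", report = .jsonable(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
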