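#' Define a gene region
#'
#' A 1-based inclusive genomic interval around a drug-target gene, extended
#' by a flank on either side (default 100 kb) when selecting cis instruments
#' or colocalization variants.
#'
#' @param gene_name gene symbol used to label outputs.
#' @param chromosome chromosome name (character).
#' @param start,end 1-based inclusive gene coordinates, `start <= end`.
#' @param flank base pairs added on either side (default 100000).
#' @return Object of class `gene_region`.
#' @export
gene_region <- function(gene_name, chromosome, start, end, flank = 1e5) {
  stopifnot(start <= end, flank >= 0)
  structure(list(gene_name = gene_name, chromosome = as.character(chromosome),
                 start = as.numeric(start), end = as.numeric(end),
                 flank = as.numeric(flank)),
            class = "gene_region")
}

#' Read a gene-region table
#'
#' Delimited text with columns `gene`, `chr`, `start`, `end`.
#'
#' @param path file path.
#' @param flank flank applied to every region.
#' @return Named list of [gene_region()] objects.
#' @export
read_gene_regions <- function(path, flank = 1e5) {
  delim <- .sniff_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE)
  regions <- lapply(seq_len(nrow(raw)), function(i) {
    gene_region(raw$gene[i], raw$chr[i], raw$start[i], raw$end[i], flank)
  })
  names(regions) <- raw$gene
  regions
}

#' Per-variant instrument strength
#'
#' The F-statistic approximation for a single-variant instrument: the square
#' of the variant-exposure association divided by the square of its standard
#' error.
#'
#' @param beta variant-exposure association(s).
#' @param se matching standard error(s), positive.
#' @return `(beta / se)^2`, vectorized.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

# Greedy p-ranked LD pruning (clumping-style): repeatedly keep the
# smallest-p candidate and discard candidates with r^2 >= r2_max against
# any kept variant. Ties in p broken by position then variant_id. Pairs
# missing from the LD matrix (or on different chromosomes) count as r = 0.
.greedy_prune <- function(records, ld, r2_max) {
  ord <- order(records$p_value, records$position, records$variant_id)
  cand <- records[ord, , drop = FALSE]
  kept <- character(0)
  have_ld <- !is.null(ld)
  in_ld <- if (have_ld) cand$variant_id %in% rownames(ld) else rep(FALSE, nrow(cand))
  active <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    vid <- cand$variant_id[i]
    kept <- c(kept, vid)
    if (have_ld && in_ld[i]) {
      rest <- which(active & seq_len(nrow(cand)) > i)
      rest <- rest[in_ld[rest] & cand$chromosome[rest] == cand$chromosome[i]]
      if (length(rest) > 0) {
        r2 <- ld[vid, cand$variant_id[rest]]^2
        active[rest[r2 >= r2_max]] <- FALSE
      }
    }
  }
  kept
}

.instrument_set <- function(label, records, rule) {
  structure(
    list(label = label,
         variant_ids = records$variant_id,
         selection_rule = rule,
         f_statistics = stats::setNames(f_statistic(records$beta, records$se),
                                        records$variant_id)),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", x$label, "\n")
  cat("  variants:", length(x$variant_ids), "\n")
  if (length(x$f_statistics) > 0) {
    cat("  min F:", signif(min(x$f_statistics), 4), "\n")
  }
  rule <- x$selection_rule
  cat("  rule: p <=", rule$p_max, ", r2 <", rule$r2_max, ",", rule$scope, "\n")
  invisible(x)
}

#' Select cis (drug-target) instruments
#'
#' Candidates are variants inside the flanked gene region reaching the
#' significance threshold; the set is pruned to low linkage disequilibrium
#' by greedy p-value-ranked clumping, removing candidates with
#' `r^2 >= r2_max` against any kept variant.
#'
#' @param exposure `summary_dataset` for the exposure trait.
#' @param region [gene_region()].
#' @param ld [ld_matrix()] covering the candidate variants.
#' @param p_max significance threshold (default genome-wide, 5e-8).
#' @param r2_max LD pruning threshold; cis default 0.1.
#' @return An `instrument_set` ordered by ascending p-value. An empty set
#'   (with a message) when no variant in the region reaches `p_max`,
#'   mirroring targets that cannot be instrumented.
#' @export
select_cis_instruments <- function(exposure, region, ld, p_max = 5e-8,
                                   r2_max = 0.1) {
  stopifnot(inherits(exposure, "summary_dataset"), inherits(region, "gene_region"))
  r <- exposure$records
  lo <- region$start - region$flank
  hi <- region$end + region$flank
  cand <- r[r$chromosome == region$chromosome & r$position >= lo &
              r$position <= hi & r$p_value <= p_max, , drop = FALSE]
  rule <- list(p_max = p_max, r2_max = r2_max, scope = "cis",
               region = region$gene_name, excluded = character(0))
  if (nrow(cand) == 0) {
    message("no genome-wide significant variants in region ", region$gene_name,
            "; target not instrumentable")
    return(.instrument_set(region$gene_name, cand, rule))
  }
  kept <- .greedy_prune(cand, ld, r2_max)
  kept_rec <- cand[match(kept, cand$variant_id), , drop = FALSE]
  .instrument_set(region$gene_name, kept_rec, rule)
}

#' Select genome-wide instruments
#'
#' The same greedy pruning rule as [select_cis_instruments()] applied to all
#' significant variants, with the stringent genome-wide independence
#' threshold (`r^2 < 0.001` by default). Variants on different chromosomes,
#' or absent from the LD matrix, are treated as uncorrelated.
#'
#' @inheritParams select_cis_instruments
#' @param label label stored on the returned set.
#' @export
select_genomewide_instruments <- function(exposure, ld = NULL, p_max = 5e-8,
                                          r2_max = 0.001,
                                          label = "genome-wide") {
  stopifnot(inherits(exposure, "summary_dataset"))
  r <- exposure$records
  cand <- r[r$p_value <= p_max, , drop = FALSE]
  rule <- list(p_max = p_max, r2_max = r2_max, scope = "genome-wide",
               excluded = character(0))
  if (nrow(cand) == 0) {
    message("no genome-wide significant variants; nothing to select")
    return(.instrument_set(label, cand, rule))
  }
  kept <- .greedy_prune(cand, ld, r2_max)
  kept_rec <- cand[match(kept, cand$variant_id), , drop = FALSE]
  .instrument_set(label, kept_rec, rule)
}

#' Remove variants from an instrument set
#'
#' Applies a user-supplied exclusion list (for example variants associated
#' with smoking or alcohol use in an external lookup) ahead of a
#' sensitivity analysis; removed ids are recorded in the selection rule.
#'
#' @param s `instrument_set`.
#' @param excluded character vector of variant ids.
#' @return The filtered `instrument_set`.
#' @export
apply_exclusions <- function(s, excluded) {
  stopifnot(inherits(s, "instrument_set"))
  excluded <- as.character(excluded)
  hit <- s$variant_ids %in% excluded
  s$selection_rule$excluded <- union(s$selection_rule$excluded,
                                     s$variant_ids[hit])
  s$variant_ids <- s$variant_ids[!hit]
  s$f_statistics <- s$f_statistics[!hit]
  s
}

#' Read an exclusion list (one variant id per line)
#'
#' @param path text file.
#' @return Character vector of variant ids.
#' @export
read_exclusions <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}
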