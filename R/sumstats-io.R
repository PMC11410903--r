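#' @keywords internal
#' @useDynLib targetmr, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Allele complement lookup used by strand-flip logic.
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "G" & oa == "C") | (ea == "C" & oa == "G")
}

#' Construct a GWAS summary dataset
#'
#' A summary dataset bundles per-variant association records for one trait
#' with trait metadata. Records violating the variant-level invariants
#' (identical alleles, non-positive standard error, allele frequency outside
#' (0, 1), p-value outside (0, 1]) are rejected.
#'
#' @param records data.frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `p_value`, `n`. `eaf` may be `NA`.
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"quantitative"` (betas in SD units) or `"binary"`
#'   (betas on the log-odds scale).
#' @param case_fraction fraction of cases, required when `trait_type` is
#'   binary.
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_name, trait_type = c("quantitative", "binary"),
                            case_fraction = NULL) {
  trait_type <- match.arg(trait_type)
  required <- c("variant_id", "chromosome", "position", "effect_allele",
                "other_allele", "eaf", "beta", "se", "p_value", "n")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (trait_type == "binary") {
    if (is.null(case_fraction) || !is.finite(case_fraction) ||
        case_fraction <= 0 || case_fraction >= 1) {
      stop("binary traits require case_fraction in (0, 1)")
    }
  } else {
    case_fraction <- NULL
  }
  records <- as.data.frame(records)[, required]
  records$variant_id <- as.character(records$variant_id)
  records$chromosome <- as.character(records$chromosome)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  ok <- .valid_records(records)
  if (any(!ok)) {
    stop(sum(!ok), " record(s) violate variant invariants; ",
         "use read_sumstats() to drop invalid rows on ingest")
  }
  if (anyDuplicated(records$variant_id)) {
    stop("duplicate variant_id in records")
  }
  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         case_fraction = case_fraction, records = records),
    class = "summary_dataset"
  )
}

# Row-level invariant check; returns a logical keep-vector.
.valid_records <- function(r) {
  valid_allele <- function(a) a %in% names(.COMPLEMENT)
  ok <- !is.na(r$variant_id) & nzchar(r$variant_id) &
    valid_allele(r$effect_allele) & valid_allele(r$other_allele) &
    r$effect_allele != r$other_allele &
    is.finite(r$beta) &
    is.finite(r$se) & r$se > 0 &
    is.finite(r$p_value) & r$p_value > 0 & r$p_value <= 1 &
    is.finite(r$position) & r$position >= 1 &
    is.finite(r$n) & r$n > 0
  ok & (is.na(r$eaf) | (r$eaf > 0 & r$eaf < 1))
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("GWAS summary dataset:", x$trait_name, sprintf("(%s)\n", x$trait_type))
  cat("  variants:", nrow(x$records), "\n")
  if (!is.null(x$case_fraction)) {
    cat("  case fraction:", signif(x$case_fraction, 4), "\n")
  }
  invisible(x)
}

# Column-name aliases accepted on ingest (GWAS-SSF style and common exports).
.COLUMN_ALIASES <- list(
  variant_id = c("variant_id", "rsid", "snp", "markername", "id"),
  chr = c("chr", "chromosome"),
  pos = c("pos", "position", "base_pair_location", "bp"),
  ea = c("ea", "effect_allele", "a1"),
  oa = c("oa", "other_allele", "non_effect_allele", "a2"),
  eaf = c("eaf", "effect_allele_frequency", "af", "freq"),
  beta = c("beta", "effect"),
  se = c("se", "standard_error", "stderr"),
  p = c("p", "pval", "p_value", "pvalue"),
  n = c("n", "sample_size", "samplesize")
)

.sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads tab- or comma-delimited summary statistics with a header row,
#' normalizes alleles to uppercase, drops rows that violate the
#' variant-level invariants (counting them in the `n_dropped` attribute),
#' and returns a [summary_dataset()].
#'
#' @param path path to a delimited text file with a header row.
#' @param trait_name,trait_type,case_fraction trait metadata, see
#'   [summary_dataset()].
#' @param column_map optional named character vector mapping the canonical
#'   names (`variant_id`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`,
#'   `p`, `n`) to the column names in the file; unmapped columns are matched
#'   against built-in aliases.
#' @return A `summary_dataset`; attribute `n_dropped` counts rows dropped
#'   for invariant violations.
#' @export
read_sumstats <- function(path, trait_name, trait_type = c("quantitative", "binary"),
                          case_fraction = NULL, column_map = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .sniff_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop("empty file (no data rows): ", path)

  lower <- tolower(names(raw))
  resolve <- function(key) {
    if (!is.null(column_map) && key %in% names(column_map)) {
      idx <- match(tolower(column_map[[key]]), lower)
      if (is.na(idx)) stop("mapped column not found for '", key, "': ",
                           column_map[[key]])
      return(idx)
    }
    idx <- match(.COLUMN_ALIASES[[key]], lower)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) return(NA_integer_)
    idx[1]
  }
  idx <- vapply(names(.COLUMN_ALIASES), resolve, integer(1))
  mandatory <- setdiff(names(.COLUMN_ALIASES), "eaf")
  absent <- mandatory[is.na(idx[mandatory])]
  if (length(absent) > 0) {
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))
  }

  records <- data.frame(
    variant_id = as.character(raw[[idx["variant_id"]]]),
    chromosome = as.character(raw[[idx["chr"]]]),
    position = as.integer(raw[[idx["pos"]]]),
    effect_allele = toupper(as.character(raw[[idx["ea"]]])),
    other_allele = toupper(as.character(raw[[idx["oa"]]])),
    eaf = if (is.na(idx["eaf"])) NA_real_ else as.numeric(raw[[idx["eaf"]]]),
    beta = as.numeric(raw[[idx["beta"]]]),
    se = as.numeric(raw[[idx["se"]]]),
    p_value = as.numeric(raw[[idx["p"]]]),
    n = as.numeric(raw[[idx["n"]]]),
    stringsAsFactors = FALSE
  )
  ok <- .valid_records(records)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message("read_sumstats: dropped ", n_dropped,
            " row(s) violating variant invariants")
  }
  records <- records[ok, , drop = FALSE]
  if (nrow(records) == 0) stop("no valid records in ", path)
  records <- records[!duplicated(records$variant_id), , drop = FALSE]
  rownames(records) <- NULL
  ds <- summary_dataset(records, trait_name, trait_type, case_fraction)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Construct an LD correlation matrix
#'
#' Signed correlations between counted-allele dosages. The matrix must be
#' symmetric (within 1e-8) with unit diagonal; signs are interpreted
#' relative to the effect-allele orientation reported in the accompanying
#' summary datasets.
#'
#' @param r square numeric matrix of signed correlations in \[-1, 1\].
#' @param variant_ids character vector labelling rows/columns of `r`.
#' @return Object of class `ld_matrix` (a matrix with dimnames).
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(variant_ids)) stop("variant_ids required (or rownames on r)")
  variant_ids <- as.character(variant_ids)
  if (nrow(r) != ncol(r) || nrow(r) != length(variant_ids)) {
    stop("r must be square with dimension equal to length(variant_ids)")
  }
  if (anyDuplicated(variant_ids)) stop("duplicate variant_ids in LD matrix")
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix not symmetric within 1e-8")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (any(r > 1 + 1e-8 | r < -1 - 1e-8)) stop("LD correlations outside [-1, 1]")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(variant_ids, variant_ids)
  class(r) <- c("ld_matrix", class(matrix()))
  r
}

#' Read an LD matrix from file
#'
#' Accepts either a square delimited matrix whose first header row holds the
#' variant ids, or a long-format three-column file (`id1`, `id2`, `r`);
#' missing long-format pairs default to 0.
#'
#' @param path delimited text file.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .sniff_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) == 3 && !all(vapply(raw, is.numeric, logical(1)))) {
    ids <- sort(unique(c(as.character(raw[[1]]), as.character(raw[[2]]))))
    r <- diag(length(ids))
    dimnames(r) <- list(ids, ids)
    i <- match(as.character(raw[[1]]), ids)
    j <- match(as.character(raw[[2]]), ids)
    r[cbind(i, j)] <- raw[[3]]
    r[cbind(j, i)] <- raw[[3]]
    return(ld_matrix(r, ids))
  }
  ld_matrix(as.matrix(raw), names(raw))
}

#' Write a summary dataset or LD matrix to delimited text
#'
#' @param ds a `summary_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ds, path) {
  stopifnot(inherits(ds, "summary_dataset"))
  out <- ds$records
  names(out) <- c("variant_id", "chr", "pos", "ea", "oa", "eaf", "beta",
                  "se", "p", "n")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Signed LD correlation between a pair; 0 when either id is absent.
.ld_r <- function(ld, id1, id2) {
  if (is.null(ld)) return(0)
  if (!(id1 %in% rownames(ld)) || !(id2 %in% rownames(ld))) return(0)
  ld[id1, id2]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every exposure instrument with the outcome dataset on a common
#' effect allele. Same-allele matches are kept; swapped alleles negate the
#' outcome beta and complement its frequency; strand complements are
#' resolved before these rules; palindromic variants (A/T, G/C) are
#' retained only when both allele frequencies lie on the same side of 0.5
#' and outside the ambiguity window; variants absent from the outcome are
#' replaced by their best LD proxy (signed-r corrected) when one reaches
#' `proxy_r2_min`, otherwise dropped.
#'
#' @param exposure `summary_dataset` holding the selected instruments.
#' @param outcome `summary_dataset` for the outcome trait.
#' @param ld optional [ld_matrix()] used for proxy lookup.
#' @param proxy_r2_min minimum r-squared for proxy substitution (default 0.8).
#' @param palindromic_window frequency window around 0.5 inside which
#'   palindromic variants are considered unresolvable (default c(0.42, 0.58)).
#' @return data.frame of class `harmonized_instruments` with one row per
#'   exposure instrument and a `harmonization_action` column in
#'   `kept`, `flipped`, `strand_flipped`, `proxy`, `dropped_palindromic`,
#'   `dropped_missing`. Dropped rows carry `NA` outcome effects; use
#'   [retained()] to subset usable instruments.
#' @export
harmonize <- function(exposure, outcome, ld = NULL, proxy_r2_min = 0.8,
                      palindromic_window = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  if (proxy_r2_min <= 0 || proxy_r2_min > 1) stop("proxy_r2_min must be in (0, 1]")
  ex <- exposure$records
  ou <- outcome$records
  ou_idx <- match(ex$variant_id, ou$variant_id)
  proxies_wanted <- any(is.na(ou_idx))
  if (proxies_wanted && is.null(ld)) {
    warning("no LD matrix supplied; variants absent from the outcome are dropped ",
            "without proxy search")
  }

  n <- nrow(ex)
  out <- data.frame(
    variant_id = ex$variant_id,
    exposure_beta = ex$beta, exposure_se = ex$se,
    outcome_beta = NA_real_, outcome_se = NA_real_,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf_exposure = ex$eaf, eaf_outcome = NA_real_,
    proxy_of = NA_character_,
    harmonization_action = NA_character_,
    stringsAsFactors = FALSE
  )

  for (i in seq_len(n)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    j <- ou_idx[i]
    if (is.na(j)) {
      out[i, ] <- .harmonize_proxy(out[i, ], ex[i, ], ou, ld, proxy_r2_min)
      next
    }
    o_ea <- ou$effect_allele[j]; o_oa <- ou$other_allele[j]
    o_beta <- ou$beta[j]; o_se <- ou$se[j]; o_eaf <- ou$eaf[j]
    action <- NA_character_

    pal <- .is_palindromic(ea, oa)
    if (!pal) {
      if (o_ea == .COMPLEMENT[ea] && o_oa == .COMPLEMENT[oa]) {
        o_ea <- ea; o_oa <- oa
        action <- "strand_flipped"
      } else if (o_ea == .COMPLEMENT[oa] && o_oa == .COMPLEMENT[ea]) {
        o_ea <- oa; o_oa <- ea
        action <- "strand_flipped"
      }
    }
    if (o_ea == ea && o_oa == oa) {
      if (is.na(action)) action <- "kept"
    } else if (o_ea == oa && o_oa == ea) {
      o_beta <- -o_beta
      if (!is.na(o_eaf)) o_eaf <- 1 - o_eaf
      if (is.na(action)) action <- "flipped"
    } else {
      # allele set mismatch: unusable record, try a proxy instead
      out[i, ] <- .harmonize_proxy(out[i, ], ex[i, ], ou, ld, proxy_r2_min)
      next
    }

    if (pal) {
      w <- palindromic_window
      e_eaf <- ex$eaf[i]
      ambiguous <- is.na(e_eaf) || is.na(o_eaf) ||
        (e_eaf > w[1] && e_eaf < w[2]) || (o_eaf > w[1] && o_eaf < w[2]) ||
        sign(e_eaf - 0.5) != sign(o_eaf - 0.5)
      if (ambiguous) {
        out$harmonization_action[i] <- "dropped_palindromic"
        next
      }
    }
    out$outcome_beta[i] <- o_beta
    out$outcome_se[i] <- o_se
    out$eaf_outcome[i] <- o_eaf
    out$harmonization_action[i] <- action
  }
  class(out) <- c("harmonized_instruments", "data.frame")
  out
}

# Proxy substitution for one exposure variant absent from (or allele-
# incompatible with) the outcome. Chooses maximal r^2, ties broken by
# position distance then lexicographic id; outcome beta sign-corrected by
# the signed LD r.
.harmonize_proxy <- function(row, ex_row, ou, ld, proxy_r2_min) {
  row$harmonization_action <- "dropped_missing"
  if (is.null(ld) || !(ex_row$variant_id %in% rownames(ld))) return(row)
  cand <- intersect(rownames(ld), ou$variant_id)
  cand <- setdiff(cand, ex_row$variant_id)
  if (length(cand) == 0) return(row)
  r <- ld[ex_row$variant_id, cand]
  keep <- which(r^2 >= proxy_r2_min)
  if (length(keep) == 0) return(row)
  cand <- cand[keep]; r <- r[keep]
  oj <- match(cand, ou$variant_id)
  dist <- abs(ou$position[oj] - ex_row$position)
  ord <- order(-r^2, dist, cand)
  best <- ord[1]
  row$outcome_beta <- sign(r[best]) * ou$beta[oj[best]]
  row$outcome_se <- ou$se[oj[best]]
  row$eaf_outcome <- ou$eaf[oj[best]]
  row$proxy_of <- cand[best]
  row$harmonization_action <- "proxy"
  row
}

#' Subset harmonized instruments to the retained rows
#'
#' @param h output of [harmonize()].
#' @return The rows whose harmonization action kept a usable outcome effect.
#' @export
retained <- function(h) {
  stopifnot(inherits(h, "harmonized_instruments"))
  out <- h[h$harmonization_action %in% c("kept", "flipped", "strand_flipped", "proxy"), ,
           drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write/read harmonized instruments
#'
#' Round-trips losslessly through tab-delimited text.
#'
#' @param h output of [harmonize()]; must be non-empty.
#' @param path output path.
#' @return `path` invisibly for the writer; a `harmonized_instruments`
#'   data.frame for the reader.
#' @export
write_harmonized <- function(h, path) {
  stopifnot(inherits(h, "harmonized_instruments"))
  if (nrow(h) == 0) stop("refusing to write an empty instrument table")
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_harmonized
#' @export
read_harmonized <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(variant_id = "character",
                                        proxy_of = "character",
                                        effect_allele = "character",
                                        other_allele = "character"))
  class(h) <- c("harmonized_instruments", "data.frame")
  h
}
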