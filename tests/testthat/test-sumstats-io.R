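# Reading, validation and harmonization of summary statistics.

write_fixture <- function(df, sep = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

base_rows <- function() {
  data.frame(variant_id = c("rs1", "rs2", "rs3"), chr = "1",
             pos = c(100, 200, 300), ea = c("A", "c", "G"),
             oa = c("G", "t", "T"), eaf = c(0.2, 0.4, 0.6),
             beta = c(0.1, -0.2, 0.05), se = c(0.01, 0.02, 0.01),
             p = c(1e-10, 1e-12, 1e-8), n = 50000)
}

test_that("well-formed files parse, alleles are uppercased, invalid rows drop", {
  path <- write_fixture(base_rows())
  ds <- read_sumstats(path, trait_name = "ldl")
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$records$effect_allele, c("A", "C", "G"))
  expect_equal(ds$records$other_allele, c("G", "T", "T"))
  expect_equal(attr(ds, "n_dropped"), 0)

  bad <- base_rows()
  bad$se[2] <- 0
  path2 <- write_fixture(bad)
  expect_message(ds2 <- read_sumstats(path2, trait_name = "ldl"), "dropped 1")
  expect_equal(nrow(ds2$records), 2)
  expect_equal(attr(ds2, "n_dropped"), 1)
})

test_that("comma delimiters, column aliases and explicit maps are accepted", {
  rows <- base_rows()
  names(rows) <- c("rsid", "chromosome", "base_pair_location", "effect_allele",
                   "other_allele", "effect_allele_frequency", "beta",
                   "standard_error", "p_value", "sample_size")
  path <- write_fixture(rows, sep = ",")
  ds <- read_sumstats(path, trait_name = "ldl")
  expect_equal(ds$records$variant_id, c("rs1", "rs2", "rs3"))

  rows2 <- base_rows()
  names(rows2)[1] <- "odd_name"
  path2 <- write_fixture(rows2)
  expect_error(read_sumstats(path2, trait_name = "x"), "variant_id")
  ds2 <- read_sumstats(path2, trait_name = "x",
                       column_map = c(variant_id = "odd_name"))
  expect_equal(nrow(ds2$records), 3)
})

test_that("empty or headers-only files are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  expect_error(read_sumstats(path, trait_name = "x"), "empty")
  writeLines("variant_id\tchr\tpos\tea\toa\teaf\tbeta\tse\tp\tn", path)
  expect_error(read_sumstats(path, trait_name = "x"), "empty")
})

test_that("summary_dataset enforces trait and record invariants", {
  expect_error(make_dataset(ids = "rs1", beta = 0.1, se = 0.01,
                            trait_type = "binary"), "case_fraction")
  rec <- make_records("rs1", 0.1, 0.01)
  rec$other_allele <- "A"
  expect_error(summary_dataset(rec, "x"), "invariant")
  rec2 <- make_records(c("rs1", "rs1"), c(0.1, 0.2), 0.01)
  expect_error(summary_dataset(rec2, "x"), "duplicate")
})

test_that("ld_matrix validates shape, symmetry and diagonal", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_s3_class(ld_matrix(r), "ld_matrix")
  r_bad <- r; r_bad[1, 2] <- 0.7
  expect_error(ld_matrix(r_bad), "symmetric")
  r_bad2 <- r; diag(r_bad2) <- c(1, 0.9)
  expect_error(ld_matrix(r_bad2), "diagonal")
  expect_error(ld_matrix(r[, 1, drop = FALSE]), "square")
})

test_that("LD matrices round-trip from square and long formats", {
  ids <- c("rs1", "rs2", "rs3")
  r <- 0.6^abs(outer(1:3, 1:3, "-"))
  dimnames(r) <- list(ids, ids)
  sq <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(r), sq, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unclass(read_ld_matrix(sq))[ids, ids], r)

  long <- data.frame(id1 = c("rs1", "rs1", "rs2"),
                     id2 = c("rs2", "rs3", "rs3"),
                     r = c(0.6, 0.36, 0.6))
  lf <- withr::local_tempfile(fileext = ".tsv")
  write.table(long, lf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unclass(read_ld_matrix(lf))[ids, ids], r, tolerance = 1e-12)
})

test_that("swapped outcome alleles flip the beta and complement the frequency", {
  ex <- make_dataset(ids = "rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G")
  ou <- make_dataset(ids = "rs1", beta = 0.05, se = 0.02, ea = "G", oa = "A",
                     eaf = 0.3)
  h <- harmonize(ex, ou)
  expect_equal(h$harmonization_action, "flipped")
  expect_equal(h$outcome_beta, -0.05)
  expect_equal(h$eaf_outcome, 0.7)
  expect_equal(h$effect_allele, "A")
})

test_that("strand complements are resolved before allele matching", {
  ex <- make_dataset(ids = c("rs1", "rs2"), beta = c(0.1, 0.1), se = 0.01,
                     ea = "A", oa = "G")
  ou <- make_dataset(ids = c("rs1", "rs2"), beta = c(0.05, 0.07), se = 0.02,
                     ea = c("T", "C"), oa = c("C", "T"), eaf = 0.3)
  # rs1: T/C is the strand complement of A/G (kept after complementing);
  # rs2: C/T is the strand complement of G/A, the swap of A/G -> beta negated
  h <- harmonize(ex, ou)
  expect_equal(h$harmonization_action, c("strand_flipped", "strand_flipped"))
  expect_equal(h$outcome_beta, c(0.05, -0.07))
})

test_that("palindromic variants follow the frequency-window rule", {
  ex <- make_dataset(ids = c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                     ea = "A", oa = "T", eaf = c(0.50, 0.20, 0.20))
  ou <- make_dataset(ids = c("rs1", "rs2", "rs3"), beta = 0.05, se = 0.02,
                     ea = "A", oa = "T", eaf = c(0.50, 0.25, 0.75))
  h <- harmonize(ex, ou)
  # eaf 0.5 is inside the window; 0.20 vs 0.25 is unambiguous;
  # 0.20 vs 0.75 puts the frequencies on opposite sides of 0.5
  expect_equal(h$harmonization_action,
               c("dropped_palindromic", "kept", "dropped_palindromic"))
  ex_na <- make_dataset(ids = "rs9", beta = 0.1, se = 0.01, ea = "G", oa = "C",
                        eaf = NA)
  ou_na <- make_dataset(ids = "rs9", beta = 0.1, se = 0.01, ea = "G", oa = "C",
                        eaf = 0.2)
  expect_equal(harmonize(ex_na, ou_na)$harmonization_action,
               "dropped_palindromic")
})

test_that("missing variants use the best signed proxy above the r2 threshold", {
  ex <- make_dataset(ids = "rs1", beta = 0.1, se = 0.01, pos = 100)
  ou <- make_dataset(ids = c("rs2", "rs3"), beta = c(0.08, 0.06), se = 0.02,
                     pos = c(150, 120))
  r <- diag(3)
  ids <- c("rs1", "rs2", "rs3")
  dimnames(r) <- list(ids, ids)
  r["rs1", "rs2"] <- r["rs2", "rs1"] <- -0.95   # r2 = 0.9025
  r["rs1", "rs3"] <- r["rs3", "rs1"] <- 0.85    # r2 = 0.7225 < 0.8
  ld <- ld_matrix(r, ids)
  h <- harmonize(ex, ou, ld = ld, proxy_r2_min = 0.8)
  expect_equal(h$harmonization_action, "proxy")
  expect_equal(h$proxy_of, "rs2")
  expect_equal(h$outcome_beta, -0.08)  # negative signed r flips the sign

  expect_warning(h2 <- harmonize(ex, ou), "no LD matrix")
  expect_equal(h2$harmonization_action, "dropped_missing")
})

test_that("proxy sign correction is consistent with a simulated shared signal", {
  # in an AR(1) region with one causal variant, dropping the causal variant
  # from the outcome and substituting its neighbour (signed r known from the
  # generator) must preserve the direction of the outcome association
  sim <- simulate_region(region_sim_config(n_variants = 20, ld_rho = 0.95,
                                           causal_mode = "shared",
                                           causal_betas = 0.08, seed = 11))
  causal <- sim$truth$causal1
  ex <- sim$trait1
  ex$records <- ex$records[ex$records$variant_id == causal, , drop = FALSE]
  ou <- sim$trait2
  direct <- ou$records$beta[ou$records$variant_id == causal]
  ou$records <- ou$records[ou$records$variant_id != causal, , drop = FALSE]
  h <- harmonize(ex, ou, ld = sim$ld, proxy_r2_min = 0.8)
  expect_equal(h$harmonization_action, "proxy")
  expect_equal(sign(h$outcome_beta), sign(direct))
  # reorienting the chosen proxy's counted allele (negating its beta and its
  # signed LD column) must leave the harmonized outcome beta unchanged
  proxy <- h$proxy_of
  ou2 <- ou
  flip_row <- ou2$records$variant_id == proxy
  ou2$records$beta[flip_row] <- -ou2$records$beta[flip_row]
  tmp <- ou2$records$effect_allele[flip_row]
  ou2$records$effect_allele[flip_row] <- ou2$records$other_allele[flip_row]
  ou2$records$other_allele[flip_row] <- tmp
  ou2$records$eaf[flip_row] <- 1 - ou2$records$eaf[flip_row]
  r2 <- unclass(sim$ld)
  r2[proxy, ] <- -r2[proxy, ]
  r2[, proxy] <- -r2[, proxy]
  diag(r2) <- 1
  h2 <- harmonize(ex, ou2, ld = ld_matrix(r2), proxy_r2_min = 0.8)
  expect_equal(h2$outcome_beta, h$outcome_beta)
})

test_that("harmonization is involution-safe and bookkeeping is complete", {
  sim <- simulate_genome(genome_sim_config(n_variants = 40, seed = 5))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_true(all(h$harmonization_action == "kept"))
  expect_equal(h$outcome_beta, sim$outcome$records$beta)
  expect_equal(nrow(retained(h)) +
                 sum(grepl("^dropped", h$harmonization_action)),
               nrow(sim$exposure$records))
})

test_that("reorienting the whole outcome dataset leaves Wald ratios unchanged", {
  sim <- simulate_genome(genome_sim_config(n_variants = 30, seed = 6))
  ou <- sim$outcome
  flipped <- ou
  flipped$records$beta <- -ou$records$beta
  flipped$records$eaf <- 1 - ou$records$eaf
  ea <- ou$records$effect_allele
  flipped$records$effect_allele <- ou$records$other_allele
  flipped$records$other_allele <- ea
  w1 <- wald_ratio(retained(harmonize(sim$exposure, ou)))
  w2 <- wald_ratio(retained(harmonize(sim$exposure, flipped)))
  expect_equal(w1, w2)
})

test_that("harmonized instruments round-trip through delimited text", {
  h <- make_harmonized(g = c(0.1, 0.2, -0.15, 0.08, 0.3),
                       G = c(0.05, -0.02, 0.01, 0.04, 0.1), se_G = 0.02)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  back <- read_harmonized(path)
  expect_equal(nrow(back), 5)
  expect_equal(back$outcome_beta, h$outcome_beta)
  expect_equal(back$variant_id, h$variant_id)
  expect_error(write_harmonized(h[0, ], path), "empty")
})
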