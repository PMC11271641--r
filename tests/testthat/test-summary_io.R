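test_that("TSV and CSV dialects with remapped headers parse identically", {
  fx <- io_fixture()
  tsv <- tempfile(fileext = ".tsv")
  write.table(fx, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  csv <- tempfile(fileext = ".csv")
  fx2 <- fx
  names(fx2) <- c("RSID", "CHROM", "BP", "A1", "A2", "FREQ", "BETA",
                  "SE", "PVAL", "N")
  write.table(fx2, csv, sep = ",", quote = FALSE, row.names = FALSE)

  a <- read_summary_stats(tsv, trait_name = "t")
  b <- read_summary_stats(csv, column_map = list(
    snp_id = "RSID", chrom = "CHROM", pos = "BP", effect_allele = "A1",
    other_allele = "A2", eaf = "FREQ", beta = "BETA", se = "SE",
    pvalue = "PVAL", n = "N"), trait_name = "t")

  expect_equal(nrow(a), 3L)
  expect_true(all(a$effect_allele %in% c("A", "C", "G", "T")))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("rows violating invariants are rejected and counted, not dropped silently", {
  fx <- io_fixture()
  fx$se[2] <- 0          # invalid standard error
  fx$p[3] <- 0           # invalid p-value
  path <- tempfile(fileext = ".tsv")
  write.table(fx, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(rec <- read_summary_stats(path), "2 row\\(s\\)")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_rejected"), 2L)
})

test_that("missing mapped columns and empty files raise informative errors", {
  fx <- io_fixture()
  fx$se <- NULL
  path <- tempfile(fileext = ".tsv")
  write.table(fx, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path), "se")

  fx2 <- io_fixture()
  fx2$se[] <- 0
  path2 <- tempfile(fileext = ".tsv")
  write.table(fx2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(read_summary_stats(path2)),
               "no parseable rows")
})

test_that("duplicate SNP ids keep the lowest-p row", {
  fx <- io_fixture()
  fx$snp[2] <- "rs1"     # duplicate with higher p than row 1
  path <- tempfile(fileext = ".tsv")
  write.table(fx, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(rec <- read_summary_stats(path), "duplicate")
  expect_equal(sum(rec$snp_id == "rs1"), 1L)
  expect_equal(rec$pvalue[rec$snp_id == "rs1"], 1e-9)
})

test_that("summary-stats round-trip through write_summary_stats", {
  sim <- simulate_two_sample(simulation_config(n_snps = 8, seed = 42))
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(sim$exposure, path)
  back <- read_summary_stats(path, trait_name = "synthetic_exposure")
  ord <- match(sim$exposure$snp_id, back$snp_id)
  expect_equal(back$beta[ord], sim$exposure$beta, tolerance = 1e-12)
  expect_equal(back$se[ord], sim$exposure$se, tolerance = 1e-12)
})

test_that("harmonize aligns, flips, complements and drops as specified", {
  expo <- summary_stats(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    effect_allele = c("A", "A", "A", "A", "A", "A"),
    other_allele  = c("G", "G", "T", "G", "G", "C"),
    beta = 0.1, se = 0.01, pvalue = 1e-9, eaf = 0.3,
    trait_name = "expo")
  outc <- summary_stats(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs6"),
    effect_allele = c("A", "G", "A", "T", "G"),
    other_allele  = c("G", "A", "T", "C", "T"),
    beta = c(0.05, 0.05, 0.05, 0.05, 0.05), se = 0.02,
    pvalue = 0.01, eaf = c(0.3, 0.7, 0.5, 0.3, 0.7),
    trait_name = "outc")
  h <- harmonize(expo, outc, palindrome_eaf_window = 0.08)

  expect_equal(h$action_taken[h$snp_id == "rs1"], "kept")
  expect_equal(h$beta_out[h$snp_id == "rs1"], 0.05)
  # swapped alleles: sign flip and frequency complement
  expect_equal(h$action_taken[h$snp_id == "rs2"], "sign_flipped")
  expect_equal(h$beta_out[h$snp_id == "rs2"], -0.05)
  expect_equal(h$eaf_out[h$snp_id == "rs2"], 0.3)
  # maximally ambiguous palindrome
  expect_equal(h$action_taken[h$snp_id == "rs3"], "dropped_palindromic")
  # opposite strand, same orientation (A/G vs T/C)
  expect_equal(h$action_taken[h$snp_id == "rs4"], "kept")
  expect_equal(h$beta_out[h$snp_id == "rs4"], 0.05)
  # absent from outcome
  expect_equal(h$action_taken[h$snp_id == "rs5"], "dropped_missing")
  # A/C exposure vs T/G outcome: complement + swap -> flip
  expect_equal(h$action_taken[h$snp_id == "rs6"], "sign_flipped")
  expect_equal(h$beta_out[h$snp_id == "rs6"], -0.05)
})

test_that("palindromes align by frequency concordance outside the window", {
  expo <- summary_stats(snp_id = c("rs1", "rs2"), effect_allele = "A",
                        other_allele = "T", beta = 0.1, se = 0.01,
                        pvalue = 1e-9, eaf = 0.2, trait_name = "e")
  outc <- summary_stats(snp_id = c("rs1", "rs2"), effect_allele = "A",
                        other_allele = "T", beta = 0.05, se = 0.02,
                        pvalue = 0.01, eaf = c(0.2, 0.8), trait_name = "o")
  h <- harmonize(expo, outc)
  expect_equal(h$action_taken[h$snp_id == "rs1"], "kept")
  expect_equal(h$beta_out[h$snp_id == "rs1"], 0.05)
  # discordant frequency: reported on the other strand, so flip
  expect_equal(h$action_taken[h$snp_id == "rs2"], "sign_flipped")
  expect_equal(h$beta_out[h$snp_id == "rs2"], -0.05)
  expect_equal(h$eaf_out[h$snp_id == "rs2"], 0.2)

  # missing frequency on either side cannot be disambiguated
  outc$eaf[1] <- NA
  h2 <- harmonize(expo, outc)
  expect_equal(h2$action_taken[h2$snp_id == "rs1"], "dropped_palindromic")
})

test_that("incompatible allele pairs are dropped and empty intersections error", {
  expo <- summary_stats(snp_id = c("rs1", "rs2"), effect_allele = "A",
                        other_allele = "G", beta = 0.1, se = 0.01,
                        pvalue = 1e-9, eaf = 0.3, trait_name = "e")
  outc <- summary_stats(snp_id = c("rs1", "rs2"),
                        effect_allele = c("A", "A"),
                        other_allele = c("C", "G"),
                        beta = 0.05, se = 0.02, pvalue = 0.01, eaf = 0.3,
                        trait_name = "o")
  h <- harmonize(expo, outc)
  expect_equal(h$action_taken[h$snp_id == "rs1"], "dropped_incompatible")

  outc_disjoint <- summary_stats(snp_id = "rs99", effect_allele = "A",
                                 other_allele = "G", beta = 0.05, se = 0.02,
                                 pvalue = 0.01, trait_name = "o")
  expect_error(harmonize(expo, outc_disjoint), "no overlapping instruments")
})

test_that("harmonization count conservation, idempotence and sign-flip involution", {
  set.seed(7)
  sim <- simulate_two_sample(simulation_config(n_snps = 20, seed = 11))
  expo <- sim$exposure
  outc <- sim$outcome
  # scramble half the outcome rows: swap alleles and negate beta
  flip <- seq_len(10)
  outc$effect_allele[flip] <- "G"
  outc$other_allele[flip] <- "A"
  outc$beta[flip] <- -outc$beta[flip]
  outc$eaf[flip] <- 1 - outc$eaf[flip]

  h <- harmonize(expo, outc)
  # count conservation: every exposure SNP accounted for exactly once
  expect_equal(nrow(h), nrow(expo))
  expect_setequal(h$snp_id, expo$snp_id)
  # involution: the label-swapped, sign-negated outcome harmonizes to the
  # same effects as the original
  h0 <- harmonize(expo, sim$outcome)
  expect_equal(h$beta_out, h0$beta_out, tolerance = 1e-12)
  expect_true(all(h$action_taken[flip] == "sign_flipped"))

  # idempotence: re-harmonizing the harmonized effects changes nothing
  kept <- harmonized_kept(h)
  expo2 <- summary_stats(snp_id = kept$snp_id, effect_allele = "A",
                         other_allele = "G", beta = kept$beta_exp,
                         se = kept$se_exp, pvalue = 1e-9,
                         eaf = kept$eaf_exp, trait_name = "e2")
  outc2 <- summary_stats(snp_id = kept$snp_id, effect_allele = "A",
                         other_allele = "G", beta = kept$beta_out,
                         se = kept$se_out, pvalue = 0.5,
                         eaf = kept$eaf_out, trait_name = "o2")
  h2 <- harmonize(expo2, outc2)
  expect_true(all(h2$action_taken == "kept"))
  expect_equal(h2$beta_out, kept$beta_out, tolerance = 1e-12)
})
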