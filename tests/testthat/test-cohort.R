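recs <- function(chrom, pos, ref, alt, id = ".") {
  data.frame(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

test_that("multiallelic sites split into per-alternate biallelic records", {
  gm <- make_geno(recs("chr1", 100, "A", "T"),
                  matrix(c("0/1", "1/1", "./."), 1), c("s1", "s2", "s3"))
  expect_equal(unname(gm$geno[, 1]), c(1L, 2L, NA))
  expect_false(gm$variants$multiallelic_split)

  tri <- make_geno(recs("chr2", 500, "C", "T,G", id = "rs10166768"),
                   matrix(c("1/2", "0/2", "0/.", "2/2"), 1),
                   paste0("s", 1:4))
  expect_equal(nrow(tri$variants), 2)
  expect_equal(tri$variants$alt, c("T", "G"))
  expect_equal(tri$variants$id, rep("rs10166768", 2))  # rsID carried to both rows
  expect_true(all(tri$variants$multiallelic_split))
  ## GT 1/2 counts one copy of each alternate; half-call 0/. is missing
  expect_equal(unname(tri$geno[, 1]), c(1L, 0L, NA, 0L))
  expect_equal(unname(tri$geno[, 2]), c(1L, 1L, NA, 2L))

  expect_warning(
    make_geno(recs("chr1", 9, "A", "<DEL>"), matrix("0/1", 1), "s1"),
    "symbolic")
})

test_that("cohort merge honours missing-to-ref semantics and preserves explicit missingness", {
  case <- make_geno(recs(c("chr1", "chr1"), c(100, 200), c("A", "C"), c("T", "G")),
                    matrix(c("0/1", "1/1", "./.", "0/0"), 2, byrow = TRUE),
                    c("c1", "c2"), cohort = "case")
  ctrl <- make_geno(recs("chr1", 100, "A", "T"),
                    matrix(c("0/0", "./."), 1), c("k1", "k2"),
                    cohort = "control")
  m <- merge_cohorts(case, ctrl, missing_to_ref = TRUE)
  expect_equal(ncol(m$geno), 2)
  ## variant at pos 200 unseen in the control file -> controls coded 0
  expect_equal(unname(m$geno[c("k1", "k2"), "chr1:200:C:G"]), c(0L, 0L))
  ## explicitly missing ./. stays missing in either mode
  expect_true(is.na(m$geno["k2", "chr1:100:A:T"]))
  expect_true(is.na(m$geno["c1", "chr1:200:C:G"]))

  m2 <- merge_cohorts(case, ctrl, missing_to_ref = FALSE)
  expect_true(all(is.na(m2$geno[c("k1", "k2"), "chr1:200:C:G"])))

  ## variant union is symmetric in argument order
  m_rev <- merge_cohorts(ctrl, case, missing_to_ref = TRUE)
  expect_setequal(m$variants$key, m_rev$variants$key)

  bad <- make_geno(recs("chr1", 100, "G", "T"), matrix("0/1", 1), "x1")
  expect_error(merge_cohorts(case, bad), "conflicting REF")
})

test_that("allele frequency excludes missing genotypes and stays unfolded", {
  expect_equal(allele_frequency(c(0, 0, 1, 2, NA)), 3 / 8)
  expect_equal(allele_frequency(c(0, 0, 0)), 0)
  expect_equal(allele_frequency(c(2, 2, 1)), 5 / 6)  # above 0.5, not folded
  expect_error(allele_frequency(c(NA, NA)), "missing")
  ## allele-count oracle on a random matrix, with sample-permutation invariance
  set.seed(3)
  codes <- sample(c(0:2, NA), 200, replace = TRUE)
  n_alt <- sum(codes, na.rm = TRUE)
  n_tot <- 2 * sum(!is.na(codes))
  expect_equal(allele_frequency(codes), n_alt / n_tot)
  expect_equal(allele_frequency(sample(codes)), allele_frequency(codes))
})

test_that("stratified split reproduces 3:2 arithmetic and is deterministic", {
  ids <- sprintf("s%03d", 1:138)
  sp <- stratified_split(ids, rep("all", 138), seed = 11)
  expect_length(sp$training, 83)   # round-half-up of 82.8
  expect_length(sp$validation, 55)
  expect_setequal(c(sp$training, sp$validation), ids)

  sp10 <- stratified_split(sprintf("t%02d", 1:10), rep(1, 10), seed = 2)
  expect_length(sp10$training, 6)

  a <- stratified_split(ids, rep(c("f", "m"), 69), n_trials = 2, seed = 5)
  b <- stratified_split(ids, rep(c("f", "m"), 69), n_trials = 2, seed = 5)
  expect_identical(a$training, b$training)
  expect_identical(a$chosen_trial, b$chosen_trial)

  ## per-stratum deviation bound |frac - 0.6| <= 1/n_s
  strata <- rep(c("a", "b", "c"), c(7, 20, 111))
  sp3 <- stratified_split(sprintf("x%03d", 1:138), strata, seed = 1)
  for (s in unique(strata)) {
    in_s <- sprintf("x%03d", 1:138)[strata == s]
    frac <- mean(in_s %in% sp3$training)
    expect_lte(abs(frac - 0.6), 1 / length(in_s) + 1e-12)
  }
})

test_that("VCF round trip: written files are re-read with identical genotypes", {
  dir <- withr::local_tempdir()
  sites <- data.frame(chrom = c("chr1", "chr1"), pos = c(11, 25),
                      id = c("rs1", "."), ref = c("A", "C"),
                      alt = c("G", "T,G"), stringsAsFactors = FALSE)
  gt <- matrix(c("0/1", "1/1", "./.",
                 "1/2", "0/0", "0/2"), 2, 3, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  f <- file.path(dir, "x.vcf")
  write_vcf(f, sites, gt)
  gm <- read_cohort_vcf(f, cohort = "case", sample_type = "blood")
  expect_equal(nrow(gm$variants), 3)  # biallelic + split tri-allelic
  expect_equal(unname(gm$geno[, "chr1:11:A:G"]), c(1L, 2L, NA))
  expect_equal(unname(gm$geno[, "chr1:25:C:T"]), c(1L, 0L, 0L))
  expect_equal(unname(gm$geno[, "chr1:25:C:G"]), c(1L, 0L, 1L))
  ## byte-identical rewrite
  f2 <- file.path(dir, "y.vcf")
  write_vcf(f2, sites, gt)
  expect_identical(unname(tools::md5sum(f)), unname(tools::md5sum(f2)))
})
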