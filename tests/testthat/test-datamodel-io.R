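# Readers/writers for summary statistics, genotypes, covariates and the
# refinement log.

test_that("scoring dialect parses, back-fills chi2 and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tBETA\tP",
               "rs1\tA\t0.12\t0.001",
               "rs2\tG\t-0.05\t0.5",
               "rs3\tT\t0.02\t1.0"), f)
  st <- read_sumstats(f, "scoring")
  expect_s3_class(st, "sumstats")
  expect_equal(nrow(st), 3)
  expect_equal(st$chi2, qchisq(st$p, 1, lower.tail = FALSE))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(st, out, "scoring")
  st2 <- read_sumstats(out, "scoring")
  expect_equal(st2$beta, st$beta)
  expect_equal(st2$p, st$p)
  expect_equal(st2$chi2, st$chi2)
})

test_that("heritability dialect parses (Z alias) and back-fills p", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tN\tZ",
               "rs1\tA\tC\t10000\t4.0",
               "rs2\tG\tT\t10000\t0.5"), f)
  st <- read_sumstats(f, "heritability")
  expect_equal(st$chi2, c(4, 0.5))
  expect_equal(st$p, pchisq(c(4, 0.5), 1, lower.tail = FALSE))
  expect_equal(st$n_eff, c(10000, 10000))
})

test_that("out-of-domain rows are dropped and counted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tBETA\tP",
               "rs1\tA\t0.1\t0",        # p = 0: out of (0, 1]
               "rs2\tN\t0.1\t0.5",      # bad allele
               "rs3\tC\t0.1\t0.01"), f)
  withr::local_options(titr.verbose = TRUE)
  expect_message(st <- read_sumstats(f, "scoring"), "dropped 2 of 3")
  expect_equal(st$snp_id, "rs3")
})

test_that("missing mandatory columns and duplicate ids are named errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tBETA", "rs1\tA\t0.1"), f)
  expect_error(read_sumstats(f, "scoring"), "column 'P'")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tBETA\tP", "rs1\tA\t0.1\t0.5", "rs1\tC\t0.2\t0.1"), g)
  expect_error(read_sumstats(g, "scoring"), "rs1")
})

test_that("sumstats constructor enforces the chi2/p consistency invariant", {
  expect_error(
    sumstats(data.frame(snp_id = "rs1", a1 = "A", p = 0.5, chi2 = 4)),
    "disagree")
  ok <- sumstats(data.frame(snp_id = "rs1", a1 = "A",
                            p = pchisq(4, 1, lower.tail = FALSE), chi2 = 4))
  expect_equal(ok$p, pchisq(4, 1, lower.tail = FALSE))
})

test_that("dosage-text genotypes round-trip, preserving one missing cell", {
  d <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3)
  rownames(d) <- c("a", "b", "c")
  snps <- data.frame(snp_id = c("rs1", "rs2"), chr = 1, pos = c(100, 200),
                     a1 = c("A", "G"), a2 = c("C", "T"))
  g <- geno_matrix(d, snps, "toy")
  expect_equal(sum(is.na(g$dosages)), 1)
  pre <- withr::local_tempfile()
  write_genotypes(g, pre)
  g2 <- read_genotypes(pre, population = "toy")
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$snps$a1, g$snps$a1)
})

test_that("random dosage matrices round-trip through both formats", {
  g <- make_geno(10, 20, seed = 7, miss = 0.05)
  pre <- withr::local_tempfile()
  write_genotypes(g, pre)
  expect_equal(read_genotypes(pre)$dosages, g$dosages)
  # PLINK binary adapter, including a non-multiple-of-4 sample count
  write_genotypes(g, pre, "plink_bed")
  g3 <- read_genotypes(pre, "plink_bed")
  expect_equal(unname(g3$dosages), unname(g$dosages))
  expect_equal(allele_freq(g3), allele_freq(g))
})

test_that("invalid genotype inputs are rejected", {
  snps <- data.frame(snp_id = "rs1", chr = 1, pos = 1, a1 = "A", a2 = "C")
  expect_error(geno_matrix(matrix(3L, 2, 1), snps), "0, 1, 2")
  expect_error(geno_matrix(matrix(0L, 2, 2), snps), "2 SNP columns")
  bad <- data.frame(snp_id = "rs1", chr = 1, pos = 1, a1 = "X", a2 = "C")
  expect_error(geno_matrix(matrix(0L, 2, 1), bad), "allele")
})

test_that("titr log round-trips exactly and validates iteration numbering", {
  empty <- titr_log_new(data.frame(), list())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_titr_log(empty, f)
  expect_equal(nrow(read_titr_log(f)$entries), 0)

  entries <- data.frame(iteration = 1:3, tissue = c("t1", "t2", "t1"),
                        bin = c(1L, 1L, 2L),
                        p_threshold = c(0.01, 0.05, 0.001),
                        n_added = c(5L, 3L, 2L),
                        n_cumulative = c(5L, 8L, 10L),
                        delta_r2_train = c(0.05, 0.02, 0.01),
                        selection_p = c(1e-5, 1e-3, 0.01),
                        delta_r2_valid = c(NA, NA, NA))
  snps <- list(sprintf("rs%d", 1:5), sprintf("rs%d", 6:8),
               sprintf("rs%d", 9:10))
  lg <- titr_log_new(entries, snps)
  write_titr_log(lg, f)
  lg2 <- read_titr_log(f)
  expect_equal(lg2$entries$n_cumulative, lg$entries$n_cumulative)
  expect_equal(lg2$snps, lg$snps)
  # cumulative count equals the running sum recomputed from the SNP lists
  expect_equal(lg2$entries$n_cumulative, cumsum(lengths(lg2$snps)))
  # gap in iteration numbering is rejected
  bad <- entries
  bad$iteration <- c(1L, 3L, 4L)
  expect_error(titr_log_new(bad, snps), "without gaps")
})

test_that("covariate and partition files round-trip", {
  cov <- data.frame(sample_id = c("a", "b"), age = c(50, 60), sex = c(0, 1),
                    pc1 = rnorm(2), coding_prs = 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_covariates(cov, f)
  expect_equal(read_covariates(f)$age, cov$age)
  p <- partition("liver", list(type = "top_fraction", value = 0.05),
                 c("rs1", "rs2"))
  g <- withr::local_tempfile(fileext = ".tsv")
  write_partition(p, g)
  p2 <- read_partition(g)
  expect_equal(p2$snp_ids, p$snp_ids)
  expect_equal(p2$selector$value, 0.05)
})

test_that("a full simulated study survives a disk round-trip", {
  st <- small_study()
  dir <- withr::local_tempdir()
  write_study(st, dir)
  st2 <- read_study(dir)
  expect_equal(st2$train$genotypes$dosages, st$train$genotypes$dosages)
  expect_equal(st2$sumstats$beta, st$sumstats$beta, tolerance = 1e-6)
  expect_equal(st2$truth$causal_snps, st$truth$causal_snps)
  expect_equal(sort(st2$tracks[[1]]$raw_score), sort(st$tracks[[1]]$raw_score),
               tolerance = 1e-6)
})
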