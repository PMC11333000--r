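# Threshold grid, allelic scoring, principal components, coding covariate.

test_that("threshold grid spans [1e-5, 1] with 370 log-uniform values", {
  g <- threshold_grid()
  expect_equal(length(g), 370)
  expect_equal(g[1], 1e-5)
  expect_equal(g[370], 1.0)
  expect_true(all(diff(g) > 0))
  ratios <- g[-1] / g[-length(g)]
  expect_lt(max(abs(ratios - ratios[1])), 1e-12)
  expect_equal(threshold_grid(2), c(1e-5, 1))
  expect_error(threshold_grid(1), "at least 2")
  expect_error(threshold_grid(10, p_min = 0), "p_min")
})

test_that("scoring follows the worked arithmetic and missing-as-zero rule", {
  d <- matrix(c(2L, 1L, 0L), nrow = 1)
  rownames(d) <- "s1"
  snps <- data.frame(snp_id = c("r1", "r2", "r3"), chr = 1,
                     pos = c(1, 2, 3) * 1000, a1 = c("A", "G", "T"),
                     a2 = c("C", "T", "G"))
  g <- geno_matrix(d, snps, "toy")
  st <- sumstats(data.frame(snp_id = c("r1", "r2", "r3"),
                            a1 = c("A", "G", "T"), a2 = c("C", "T", "G"),
                            beta = c(0.1, -0.2, 0.3), p = c(0.5, 0.5, 0.5)))
  pr <- compute_prs(g, st, p_threshold = 1)
  expect_equal(pr$score, 2 * 0.1 + 1 * (-0.2) + 0 * 0.3)
  # missing dosage at the 0.3-beta SNP still contributes exactly 0
  d2 <- matrix(c(2L, 1L, NA), nrow = 1, dimnames = list("s1", NULL))
  g2 <- geno_matrix(d2, snps, "toy")
  pr2 <- compute_prs(g2, st, p_threshold = 1)
  expect_equal(pr2$score, 0.0)
  # empty surviving set
  pr0 <- compute_prs(g, st, p_threshold = 1e-6)
  expect_equal(pr0$score, 0)
  expect_equal(attr(pr0, "snp_count"), 0)
})

test_that("alleles are harmonized: swapped flips beta, ambiguous dropped", {
  d <- matrix(c(2L, 0L, 1L, 1L), nrow = 1, dimnames = list("s1", NULL))
  snps <- data.frame(snp_id = c("r1", "r2", "r3", "r4"), chr = 1,
                     pos = 1:4 * 1000, a1 = c("A", "G", "A", "C"),
                     a2 = c("C", "T", "T", "A"))
  g <- geno_matrix(d, snps, "toy")
  st <- sumstats(data.frame(
    snp_id = c("r1", "r2", "r3", "r4"),
    a1 = c("C", "G", "A", "C"),          # r1 swapped, r3 ambiguous (A/T)
    a2 = c("A", "T", "T", "G"),          # r4 alleles irreconcilable
    beta = c(0.5, 0.2, 0.9, 0.9), p = rep(0.5, 4)))
  h <- harmonize_sumstats(st, g)
  expect_equal(h$snp_id, c("r1", "r2"))
  expect_equal(h$beta, c(-0.5, 0.2))
  expect_equal(attr(h, "dropped_ambiguous"), 1)
  expect_equal(attr(h, "dropped_mismatch"), 1)
})

test_that("scoring equals a brute-force dot product on random fixtures", {
  for (s in 1:8) {
    g <- make_geno(25, 40, seed = s, miss = 0.08)
    set.seed(s + 100)
    st <- sumstats(data.frame(snp_id = g$snps$snp_id, a1 = g$snps$a1,
                              a2 = g$snps$a2, beta = rnorm(40),
                              p = runif(40)))
    thr <- runif(1)
    snps <- sample(g$snps$snp_id, 30)
    pr <- compute_prs(g, st, snps, thr)
    keep <- st$snp_id %in% snps & st$p <= thr
    expected <- sapply(seq_len(25), function(i) {
      tot <- 0
      for (j in which(keep)) {
        dd <- g$dosages[i, st$snp_id[j]]
        if (!is.na(dd)) tot <- tot + dd * st$beta[j]
      }
      tot
    })
    expect_equal(pr$score, unname(expected))
    expect_equal(attr(pr, "snp_count"), sum(keep))
  }
})

test_that("snp_count is non-decreasing in the threshold", {
  g <- make_geno(20, 50, seed = 11)
  set.seed(11)
  st <- sumstats(data.frame(snp_id = g$snps$snp_id, a1 = g$snps$a1,
                            a2 = g$snps$a2, beta = rnorm(50), p = runif(50)))
  counts <- vapply(threshold_grid(25), function(t) {
    attr(compute_prs(g, st, p_threshold = t), "snp_count")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("principal components are orthogonal, deterministic and separate
           structured subpopulations", {
  g <- make_geno(80, 120, seed = 12)
  pcs <- compute_pcs(g, k = 5)
  S <- as.matrix(pcs[, -1])
  cp <- crossprod(S)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_identical(compute_pcs(g, k = 5), pcs)
  expect_error(compute_pcs(g, k = 80), "smaller")

  # two populations with diverged frequencies: PC1 separates the labels
  set.seed(13)
  f1 <- runif(150, 0.1, 0.5)
  shift <- sample(c(-0.25, 0.25), 150, replace = TRUE)
  f2 <- pmin(pmax(f1 + shift, 0.05), 0.95)
  d <- rbind(sapply(f1, function(f) rbinom(100, 2, f)),
             sapply(f2, function(f) rbinom(100, 2, f)))
  d <- matrix(as.integer(d), 200, 150,
              dimnames = list(sprintf("s%03d", 1:200), NULL))
  gp <- geno_matrix(d, data.frame(snp_id = sprintf("m%03d", 1:150),
                                  chr = 1, pos = 1:150 * 1000,
                                  a1 = "A", a2 = "C"), "mix")
  pc <- compute_pcs(gp, k = 2)
  lab <- rep(c(0, 1), each = 100)
  expect_gt(abs(cor(pc$pc1, lab)), 0.9)
})

test_that("the coding covariate is an optimized P+T model over the grid", {
  st <- small_study()
  clumps <- clump(st$sumstats, st$panel)
  grid <- threshold_grid(60)
  # flag half the causal SNPs as coding: the covariate must carry signal
  set.seed(21)
  coding <- c(sample(st$truth$causal_snps, 40),
              sample(setdiff(st$sumstats$snp_id, st$truth$causal_snps), 40))
  cov0 <- st$train$covariates[, setdiff(names(st$train$covariates),
                                        "coding_prs")]
  out <- build_coding_covariate(st$train$genotypes, st$sumstats, coding,
                                st$train$phenotype, cov0, clumps,
                                target_genotypes = st$valid$genotypes,
                                grid = grid)
  expect_true(out$p_threshold %in% grid)
  expect_gt(out$delta_r2_train, 0)
  expect_equal(nrow(out$target), nrow(st$valid$genotypes$dosages))
  # empty coding set degrades to a zero profile with a warning
  expect_warning(
    z <- build_coding_covariate(st$train$genotypes, st$sumstats,
                                character(0), st$train$phenotype, cov0,
                                clumps, grid = grid),
    "empty")
  expect_true(all(z$train$score == 0))
})
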