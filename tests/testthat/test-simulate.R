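# Synthetic two-population study generator.

test_that("genotype simulation is deterministic and respects LD contrast", {
  cfg <- sim_config(seed = 5, n_snps = 300, n_blocks = 30, n_tissues = 3,
                    n_causal = 20, causal_tissues = "tissue01")
  g1 <- simulate_genotypes(cfg, "train", 200)
  g2 <- simulate_genotypes(cfg, "train", 200)
  expect_identical(g1$dosages, g2$dosages)

  adj_r2 <- function(geno) {
    d <- geno$dosages
    storage.mode(d) <- "double"
    blk <- geno$snps$block
    r <- c()
    for (j in seq_len(ncol(d) - 1)) {
      if (blk[j] == blk[j + 1]) r <- c(r, cor(d[, j], d[, j + 1])^2)
    }
    r
  }
  cfg0 <- sim_config(seed = 6, n_snps = 200, n_blocks = 20,
                     block_rho_train = 0, n_tissues = 2, n_causal = 10,
                     causal_tissues = "tissue01")
  r0 <- adj_r2(simulate_genotypes(cfg0, "train", 2000))
  expect_lt(mean(sqrt(r0)), 0.05)   # independence limit

  cfgc <- sim_config(seed = 7, n_snps = 200, n_blocks = 20,
                     block_rho_train = 0.95, block_rho_target = 0.4,
                     n_tissues = 2, n_causal = 10,
                     causal_tissues = "tissue01")
  rtr <- adj_r2(simulate_genotypes(cfgc, "train", 2000))
  rtg <- adj_r2(simulate_genotypes(cfgc, "target", 2000))
  expect_gt(mean(rtr), mean(rtg))
  expect_error(sim_config(block_rho_train = 1), "\\[0, 1\\)")
})

test_that("SNP metadata is shared across populations and cohorts", {
  cfg <- sim_config(seed = 8, n_snps = 100, n_blocks = 10, n_tissues = 2,
                    n_causal = 5, causal_tissues = "tissue01")
  a <- simulate_genotypes(cfg, "train", 50)
  b <- simulate_genotypes(cfg, "target", 50)
  expect_identical(a$snps, b$snps)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_false(any(a$snps$a2 == comp[a$snps$a1]))  # no ambiguous pairs
})

test_that("annotation enrichment concentrates causal SNPs as configured", {
  cfg <- sim_config(seed = 9, n_snps = 50000, n_blocks = 2000,
                    n_causal = 500, enrichment = 20, n_tissues = 3,
                    causal_tissues = "tissue01")
  map <- sim_snp_map(cfg)
  causal <- sample(map$snp_id, 500)
  tracks <- simulate_annotations(cfg, causal, map$snp_id)
  t1 <- tracks[[1]]
  n_top <- sum(causal %in% t1$snp_id[t1$bin <= 10])  # top 1% bin band
  # expected 500 * 0.2 = 100 with binomial noise
  expect_gt(n_top, 100 - 4 * sqrt(500 * 0.2 * 0.8))
  expect_lt(n_top, 100 + 4 * sqrt(500 * 0.2 * 0.8))
  # non-causal tissue: membership independent of causal status
  t3 <- tracks[[3]]
  tab <- table(causal_status = t1$snp_id %in% causal,
               top = t3$snp_id %in% t3$snp_id[t3$bin <= 10])
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
  expect_error(
    simulate_annotations(sim_config(seed = 1), causal_snps = "rsX"),
    "subset")
})

test_that("no enrichment leaves causal SNPs uniform over bins", {
  cfg <- sim_config(seed = 10, n_snps = 20000, n_blocks = 1000,
                    n_causal = 400, enrichment = 1, n_tissues = 2,
                    causal_tissues = "tissue01")
  map <- sim_snp_map(cfg)
  causal <- sample(map$snp_id, 400)
  tr <- simulate_annotations(cfg, causal, map$snp_id)[[1]]
  bins <- tr$bin[match(causal, tr$snp_id)]
  counts <- table(cut(bins, breaks = seq(0, 1000, by = 100)))
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("phenotype decomposition matches the configured heritability", {
  cfg0 <- sim_config(seed = 11, n_snps = 400, n_blocks = 40, h2 = 0,
                     n_causal = 50, n_tissues = 2,
                     causal_tissues = "tissue01")
  g <- simulate_genotypes(cfg0, "train", 1000)
  causal <- sample(g$snps$snp_id, 50)
  eff <- setNames(rnorm(50, 0, 0.1), causal)
  ph0 <- simulate_phenotype(g, cfg0, eff, with_pcs = FALSE)
  d <- g$dosages[, causal]
  storage.mode(d) <- "double"
  gval <- as.vector(scale(d) %*% eff)
  expect_lt(abs(coef(lm(ph0$phenotype ~ gval))[2]), 0.05)

  cfg5 <- sim_config(seed = 12, n_snps = 400, n_blocks = 40, h2 = 0.5,
                     n_causal = 50, causal_per_locus = 1, n_tissues = 2,
                     causal_tissues = "tissue01")
  g5 <- simulate_genotypes(cfg5, "train", 4000)
  causal5 <- sample_causal_snps(cfg5)
  eff5 <- draw_effects(cfg5, causal5)
  ph5 <- simulate_phenotype(g5, cfg5, eff5, with_pcs = FALSE)
  d5 <- g5$dosages[, causal5]
  storage.mode(d5) <- "double"
  gv <- as.vector(scale(d5) %*% eff5)
  ratio <- var(gv) / var(ph5$phenotype - 0.1 * ph5$covariates$sex -
                           0.05 * scale(ph5$covariates$age))
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 0.55)
})

test_that("binary traits keep an exact control:case design", {
  cfg <- sim_config(seed = 13, n_snps = 200, n_blocks = 20, h2 = 0.3,
                    n_causal = 20, trait_type = "binary", prevalence = 0.1,
                    control_case_ratio = 4, n_tissues = 2,
                    causal_tissues = "tissue01")
  g <- simulate_genotypes(cfg, "train", 1000)
  set.seed(3)
  causal <- sample(g$snps$snp_id, 20)
  eff <- setNames(rnorm(20, 0, 0.1), causal)
  ph <- simulate_phenotype(g, cfg, eff, with_pcs = FALSE)
  n_cases <- sum(ph$phenotype == 1)
  expect_equal(sum(ph$phenotype == 0), floor(4) * n_cases)
  expect_equal(length(ph$sample_ids), length(ph$phenotype))
  cfg_bad <- sim_config(seed = 13, n_snps = 200, n_blocks = 20, h2 = 0.3,
                        n_causal = 20, trait_type = "binary",
                        prevalence = 0.45, control_case_ratio = 4,
                        n_tissues = 2, causal_tissues = "tissue01")
  expect_error(simulate_phenotype(g, cfg_bad, eff, with_pcs = FALSE),
               "controls")
})

test_that("marginal GWAS is calibrated under the null and exact in form", {
  cfg <- sim_config(seed = 14, n_snps = 50000, n_blocks = 5000,
                    block_rho_train = 0.3, n_tissues = 2, n_causal = 10,
                    causal_tissues = "tissue01")
  g <- simulate_genotypes(cfg, "train", 120)
  set.seed(1)
  y <- setNames(rnorm(120), rownames(g$dosages))
  st <- simulate_gwas(g, y)
  frac <- mean(st$p < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
  # chi2 equals the squared t statistic of the per-SNP regression
  for (j in c(1, 101, 5001)) {
    fit <- lm(y ~ g$dosages[, st$snp_id[j]])
    expect_equal(st$chi2[j], unname(summary(fit)$coefficients[2, "t value"]^2),
                 tolerance = 1e-10)
  }
})

test_that("a strong single causal SNP tops the GWAS", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(seed = 100 + s, n_snps = 200, n_blocks = 40,
                      h2 = 0.3, n_causal = 1, n_tissues = 2,
                      causal_tissues = "tissue01")
    g <- simulate_genotypes(cfg, "train", 5000)
    causal <- sample(g$snps$snp_id, 1)
    ph <- simulate_phenotype(g, cfg, setNames(sqrt(0.3), causal),
                             with_pcs = FALSE)
    st <- simulate_gwas(g, ph$phenotype)
    if (st$snp_id[which.min(st$p)] == causal) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("mean chi2 matches the LD score regression expectation", {
  # infinitesimal architecture: every SNP causal
  cfg <- sim_config(seed = 15, n_snps = 2000, n_blocks = 200, h2 = 0.4,
                    n_causal = 2000, causal_per_locus = 1, n_tissues = 2,
                    causal_tissues = "tissue01", n_panel = 400)
  g <- simulate_genotypes(cfg, "train", 4000)
  causal <- g$snps$snp_id
  eff <- draw_effects(cfg, causal)
  ph <- simulate_phenotype(g, cfg, eff, with_pcs = FALSE)
  st <- simulate_gwas(g, ph$phenotype)
  panel <- simulate_genotypes(cfg, "train", 400, "panel")
  lds <- compute_ld_scores(panel)
  # in-sample GWAS also tags all out-of-window SNPs at the 1/n sampling
  # floor, adding N * h2 * (M - wbar) / (n * M) to the expectation
  sizes <- table(panel$snps$block)
  wbar <- sum(sizes^2) / 2000
  n_gwas <- mean(st$n_eff)
  expected <- 1 + n_gwas * cfg$h2 * mean(lds$ell[, "base"]) / 2000 +
    n_gwas * cfg$h2 * (2000 - wbar) / (n_gwas * 2000)
  expect_lt(abs(mean(st$chi2) / expected - 1), 0.1)
})

test_that("the full study generator is deterministic end to end", {
  cfg <- small_study_config()
  st1 <- small_study()
  st2 <- simulate_study(cfg)
  expect_identical(st1$sumstats$chi2, st2$sumstats$chi2)
  expect_identical(st1$train$phenotype, st2$train$phenotype)
  expect_identical(st1$truth$causal_snps, st2$truth$causal_snps)
  expect_identical(st1$tracks[[2]]$bin, st2$tracks[[2]]$bin)
})
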