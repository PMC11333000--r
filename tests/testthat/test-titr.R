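# Orchestration: single-tissue models, the refinement loop, validation.

test_that("the fast screening path reproduces the lm-based tests exactly", {
  set.seed(1)
  n <- 150
  ids <- sprintf("s%03d", 1:n)
  X0 <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5), pc1 = rnorm(n))
  y <- setNames(rnorm(n) + 0.3 * X0$age, ids)
  covs <- cbind(data.frame(sample_id = ids), X0)
  S <- matrix(rnorm(n * 5), n, 5)
  cur_score <- rnorm(n)

  null_ctx <- titr:::.design_context(as.numeric(y), X0)
  cur_ctx <- titr:::.design_context(as.numeric(y), cbind(X0, s = cur_score))
  null_m <- fit_model(y, covs)
  cur_m <- fit_model(y, covs, data.frame(s = cur_score))

  scr_a <- titr:::.screen_scores(S, null_ctx, test = "anova")
  scr_j <- titr:::.screen_scores(S, null_ctx, cur_ctx, test = "jtest")
  for (j in 1:5) {
    full <- fit_model(y, covs, data.frame(cand = S[, j]))
    expect_equal(scr_a$adj_r2[j], full$adj_r2, tolerance = 1e-10)
    expect_equal(scr_a$delta_r2[j], delta_r2(full, null_m),
                 tolerance = 1e-10)
    expect_equal(scr_a$p[j], as.numeric(anova_nested(null_m, full)),
                 tolerance = 1e-10)
    expect_equal(scr_j$p[j], as.numeric(j_test(cur_m, full)),
                 tolerance = 1e-10)
    expect_equal(scr_j$delta_r2[j], delta_r2(full, cur_m),
                 tolerance = 1e-10)
  }
})

test_that("standard-mode P+T recovers a strong single causal SNP", {
  cfg <- sim_config(seed = 31, n_snps = 300, n_blocks = 40, h2 = 0.25,
                    n_causal = 1, causal_per_locus = 1, n_tissues = 2,
                    n_gwas = 4000, n_train = 600, n_panel = 200,
                    causal_tissues = "tissue01")
  st <- simulate_study(cfg)
  rep <- run_single_tissue(st$sumstats, st$panel, st$train,
                           mode = "standard", grid = threshold_grid(40))
  causal <- st$truth$causal_snps
  blk <- st$panel$snps$block[match(causal, st$panel$snps$snp_id)]
  same_block <- st$panel$snps$snp_id[st$panel$snps$block == blk]
  expect_true(any(rep$best$snps %in% same_block))
  expect_lt(rep$best$p_threshold, 0.01)
})

test_that("partitions nest: the 50% partition contains the 1% survivors", {
  st <- small_study()
  tr <- st$tracks[[1]]
  clumps <- clump(st$sumstats, st$panel)
  part50 <- top_fraction_partition(tr, 0.5)$snp_ids
  sel01 <- block_sample(clumps, top_fraction_partition(tr, 0.01)$snp_ids)
  h <- harmonize_sumstats(st$sumstats, st$train$genotypes)
  survivors <- intersect(sel01, h$snp_id[h$p <= 0.05])
  expect_true(all(survivors %in% part50))
})

test_that("zero-heritability studies terminate before any iteration", {
  cfg <- sim_config(seed = 33, n_snps = 800, n_blocks = 80, h2 = 0,
                    n_causal = 40, n_tissues = 6, n_gwas = 1200,
                    n_train = 300, n_valid = 200, n_panel = 200,
                    causal_tissues = c("tissue01", "tissue02"))
  st <- simulate_study(cfg)
  state <- run_titr(st$sumstats, st$panel, st$train, st$tracks,
                    config = titr_config(max_iterations = 5,
                                         n_jackknife_blocks = 16))
  expect_equal(state$status, "no_enriched_tissue")
  expect_equal(nrow(state$log$entries), 0)
  expect_equal(length(state$model_snps), 0)
})

test_that("the refinement loop honors its acceptance contract", {
  st <- small_study()
  cfgt <- titr_config(max_iterations = 10, n_jackknife_blocks = 20,
                      n_thresholds = 80)
  state <- run_titr(st$sumstats, st$panel, st$train, st$tracks,
                    config = cfgt)
  ent <- state$log$entries
  expect_gt(nrow(ent), 0)
  expect_true(all(ent$delta_r2_train > 0))
  expect_true(all(ent$selection_p < cfgt$alpha))
  expect_equal(ent$n_cumulative, cumsum(ent$n_added))
  expect_true(all(diff(ent$n_cumulative) > 0))
  expect_true(all(ent$tissue %in% state$candidates))
  # one SNP per LD block across the cumulative model
  u <- titr:::clump_universe(state$clumps)
  blocks <- u$block[match(state$model_snps, u$snp_id)]
  expect_false(any(duplicated(blocks)))

  # validation fills the trace deterministically
  v1 <- validate_titr(state, st$valid)
  v2 <- validate_titr(state, st$valid)
  expect_identical(attr(v1, "trace"), attr(v2, "trace"))
  expect_equal(nrow(attr(v1, "trace")), nrow(ent))
  expect_false(anyNA(v1$log$entries$delta_r2_valid))

  # the log round-trips through disk
  f <- withr::local_tempfile(fileext = ".tsv")
  write_titr_log(v1$log, f)
  expect_equal(read_titr_log(f)$entries, v1$log$entries, tolerance = 1e-12)
})

test_that("snp_overlap covers the boundary conventions", {
  expect_equal(snp_overlap(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(snp_overlap(c("a", "b"), c("c")), 0.0)
  expect_warning(z <- snp_overlap(character(0), "a"), "empty")
  expect_equal(z, 0)
  expect_equal(snp_overlap(c("a", "b", "c", "c"), c("b", "c")), 2 / 3)
})

test_that("an organism-wide track drives the surf-like mode", {
  st <- small_study()
  rep <- run_single_tissue(st$sumstats, st$panel, st$train,
                           mode = "surf_like", track = st$tracks[[1]],
                           grid = threshold_grid(40))
  expect_equal(rep$tissue, st$tracks[[1]]$tissue_label)
  expect_equal(nrow(rep$table), 5)
  expect_true(rep$best$fraction %in% c(0.01, 0.05, 0.10, 0.20, 0.50))
  expect_true(all(rep$best$snps %in%
                    top_fraction_partition(st$tracks[[1]],
                                           rep$best$fraction)$snp_ids))
})

test_that("lead-tissue mode demands a significant candidate", {
  st <- small_study()
  fake <- data.frame(tissue = c("t1", "t2"), tau_star = c(-1, 0.1),
                     tau_star_p = c(0.5, 0.9))
  expect_error(
    run_single_tissue(st$sumstats, st$panel, st$train, mode = "tissue",
                      tracks = st$tracks, fits = fake,
                      grid = threshold_grid(20)),
    "standard")
})
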