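# Shared fixtures and independent oracle implementations.

options(titr.verbose = FALSE)

# random genotype matrix with plausible metadata
make_geno <- function(n, m, seed = 1, miss = 0, maf = NULL) {
  set.seed(seed)
  maf <- maf %||% runif(m, 0.1, 0.5)
  d <- sapply(maf, function(f) rbinom(n, 2, f))
  if (miss > 0) d[runif(n * m) < miss] <- NA
  d <- matrix(as.integer(d), n, m)
  rownames(d) <- sprintf("s%03d", seq_len(n))
  snps <- data.frame(snp_id = sprintf("snp%04d", seq_len(m)),
                     chr = 1L, pos = seq_len(m) * 1000,
                     a1 = "A", a2 = "C", stringsAsFactors = FALSE)
  geno_matrix(d, snps, "test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force stratified LD scores: double loop over all in-window pairs
brute_ld_scores <- function(panel, A, window_kb) {
  ord <- order(panel$snps$chr, panel$snps$pos)
  snps <- panel$snps[ord, ]
  D <- panel$dosages[, ord, drop = FALSE]
  storage.mode(D) <- "double"
  A <- as.matrix(A)[ord, , drop = FALSE]
  m <- ncol(D)
  ell <- matrix(0, m, ncol(A))
  win <- window_kb * 1000
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (snps$chr[j] != snps$chr[k]) next
      if (abs(snps$pos[j] - snps$pos[k]) > win) next
      r <- suppressWarnings(cor(D[, j], D[, k],
                                use = "pairwise.complete.obs"))
      if (is.na(r)) r <- 0
      ell[j, ] <- ell[j, ] + A[k, ] * r^2
    }
  }
  rownames(ell) <- snps$snp_id
  ell
}

# independent PLINK-style greedy clumping (plain loops, no shared code)
ref_clump <- function(stats, panel, r2_threshold = 0.2, window_kb = 250,
                      p_ceiling = 1.0) {
  common <- intersect(stats$snp_id, panel$snps$snp_id)
  gi <- match(common, panel$snps$snp_id)
  frq <- colMeans(panel$dosages, na.rm = TRUE) / 2
  mono <- common[frq[gi] %in% c(0, 1)]
  df <- data.frame(snp_id = common, p = stats$p[match(common, stats$snp_id)],
                   chr = panel$snps$chr[gi], pos = panel$snps$pos[gi],
                   stringsAsFactors = FALSE)
  df <- df[!df$snp_id %in% mono, ]
  df <- df[order(df$p, df$chr, df$pos, df$snp_id), ]
  assigned <- character(0)
  blocks <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$snp_id[i]
    if (id %in% assigned || df$p[i] > p_ceiling) next
    members <- character(0)
    for (k in seq_len(nrow(df))) {
      kid <- df$snp_id[k]
      if (kid == id || kid %in% assigned) next
      if (df$chr[k] != df$chr[i]) next
      if (abs(df$pos[k] - df$pos[i]) > window_kb * 1000) next
      x <- panel$dosages[, id]
      y <- panel$dosages[, kid]
      r <- suppressWarnings(cor(x, y, use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 >= r2_threshold) members <- c(members, kid)
    }
    members <- members[order(df$p[match(members, df$snp_id)], members)]
    blocks[[length(blocks) + 1]] <- list(index_snp = id, members = members)
    assigned <- c(assigned, id, members)
  }
  blocks
}

block_set_signature <- function(blocks) {
  sig <- vapply(blocks, function(b) {
    paste(b$index_snp, paste(sort(b$members), collapse = ","), sep = "|")
  }, character(1))
  sort(sig)
}

# craft a clump_result directly (for block_sample contract tests)
make_clumps <- function(blocks, p, unassigned = character()) {
  assign <- data.frame(
    snp_id = unlist(lapply(blocks, function(b) c(b$index_snp, b$members))),
    block = rep(seq_along(blocks),
                vapply(blocks, function(b) 1L + length(b$members), 1L)),
    is_index = unlist(lapply(blocks, function(b) {
      c(TRUE, rep(FALSE, length(b$members)))
    })),
    stringsAsFactors = FALSE)
  assign$p <- unname(p[assign$snp_id])
  structure(list(blocks = blocks, assign = assign, unassigned = unassigned,
                 r2_threshold = 0.2, window_kb = 250, p = p),
            class = "clump_result")
}

# small deterministic study reused across expensive unit tests
.small_study_env <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(.small_study_env$study)) {
    cfg <- sim_config(seed = 42, n_snps = 2000, n_blocks = 150,
                      n_gwas = 3000, n_train = 800, n_valid = 400,
                      n_panel = 300, h2 = 0.4, n_causal = 150,
                      causal_per_locus = 3, n_tissues = 6,
                      causal_tissues = c("tissue01", "tissue02"))
    .small_study_env$study <- simulate_study(cfg)
    .small_study_env$config <- cfg
  }
  .small_study_env$study
}
small_study_config <- function() {
  invisible(small_study())
  .small_study_env$config
}

# regression fixture: phenotype + covariates for n samples
make_cohort_frame <- function(n, seed = 1, k_cov = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * k_cov), n, k_cov)
  colnames(X) <- paste0("c", seq_len(k_cov))
  ids <- sprintf("s%04d", seq_len(n))
  y <- setNames(as.vector(X %*% runif(k_cov, -0.3, 0.3)) + rnorm(n), ids)
  list(phenotype = y,
       covariates = cbind(data.frame(sample_id = ids), as.data.frame(X)),
       X = X)
}
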