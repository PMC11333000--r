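# Internal fast paths for threshold screening.
#
# All candidate models differ from a fixed design by a single added score
# column, so adjusted R^2, the nested-model F test and the J test reduce
# to partial-regression algebra on residualized columns.  The lm-based
# public functions in select.R are the reference; equality of the two
# routes is asserted in the test suite.

# QR context for a design matrix (with intercept prepended); constant
# columns are dropped as uninformative
.design_context <- function(y, X) {
  X <- as.matrix(X)
  keep <- apply(X, 2, function(x) var(x) > 0)
  X <- cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) stopf("rank-deficient design in screening path")
  Q <- qr.Q(qx)
  fitted <- Q %*% crossprod(Q, y)
  res <- y - fitted
  list(X = X, Q = Q, y = y, fitted = as.vector(fitted),
       resid = as.vector(res), rss = sum(res^2),
       tss = sum((y - mean(y))^2), n = length(y), q = ncol(X))
}

.adj_r2_from_rss <- function(rss, tss, n, q) {
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - q)
}

# Screen a matrix of candidate score columns S against a null context
# (covariates only) and a current context (covariates + current PRS).
# Returns per-column adjusted R^2 of [covariates + s], delta over the
# current model, and the selection p (ANOVA when `test == "anova"`,
# Davidson-MacKinnon J against the current model otherwise).
.screen_scores <- function(S, null_ctx, current_ctx = NULL,
                           test = c("anova", "jtest")) {
  test <- match.arg(test)
  S <- as.matrix(S)
  n <- null_ctx$n
  RS <- S - null_ctx$Q %*% crossprod(null_ctx$Q, S)
  a <- as.vector(crossprod(RS, null_ctx$resid))
  ss <- colSums(RS^2)
  gain <- ifelse(ss > n * 1e-12, a^2 / ss, 0)
  rss_full <- pmax(null_ctx$rss - gain, 0)
  adj_full <- .adj_r2_from_rss(rss_full, null_ctx$tss, n, null_ctx$q + 1)
  if (test == "anova") {
    df2 <- n - null_ctx$q - 1
    f <- (null_ctx$rss - rss_full) / (rss_full / df2)
    p <- ifelse(ss > n * 1e-12, pf(f, 1, df2, lower.tail = FALSE), 1)
    cur_adj <- .adj_r2_from_rss(null_ctx$rss, null_ctx$tss, n, null_ctx$q)
  } else {
    stopifnot(!is.null(current_ctx))
    # challenger fitted values: fitted of y on [covariates, s]
    Fhat <- null_ctx$fitted + sweep(RS, 2, ifelse(ss > n * 1e-12, a / ss, 0),
                                    "*")
    RF <- Fhat - current_ctx$Q %*% crossprod(current_ctx$Q, Fhat)
    ac <- as.vector(crossprod(RF, current_ctx$resid))
    ssc <- colSums(RF^2)
    df2 <- n - current_ctx$q - 1
    rss_aug <- pmax(current_ctx$rss - ifelse(ssc > n * 1e-12, ac^2 / ssc, 0), 0)
    t2 <- (current_ctx$rss - rss_aug) / (rss_aug / df2)
    p <- ifelse(ssc > n * 1e-12, 2 * pt(-sqrt(pmax(t2, 0)), df2), 1)
    cur_adj <- .adj_r2_from_rss(current_ctx$rss, current_ctx$tss, n,
                                current_ctx$q)
  }
  data.frame(adj_r2 = adj_full, delta_r2 = adj_full - cur_adj, p = p)
}

# Cumulative score columns for a p-ordered SNP set at each threshold of a
# grid.  `D` is samples x SNPs with missing already zeroed, columns in
# ascending-p order, `beta` aligned, `p_sorted` ascending.  Returns the
# score matrix for the distinct non-zero SNP counts hit by the grid plus
# the mapping back to grid entries.
.threshold_scores <- function(D, beta, p_sorted, grid) {
  counts <- findInterval(grid, p_sorted)
  ucounts <- sort(unique(counts[counts > 0]))
  if (length(ucounts) == 0) {
    return(list(S = NULL, counts = counts, ucounts = ucounts))
  }
  cum <- sweep(D, 2, beta, "*")
  if (ncol(cum) > 1) {
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1]
  }
  S <- cum[, ucounts, drop = FALSE]
  list(S = S, counts = counts, ucounts = ucounts)
}

# Full P+T optimization of one SNP set over a threshold grid against the
# covariate-only null model.  Returns the best threshold (smallest grid
# value attaining the maximal delta adjusted R^2), its statistics and the
# surviving SNPs.
.pt_optimize <- function(genotypes, hstats, snp_set, phenotype, covariates,
                         grid) {
  ids <- names(phenotype)
  X0 <- covariates[match(ids, covariates$sample_id),
                   setdiff(names(covariates), "sample_id"), drop = FALSE]
  ctx <- .design_context(as.numeric(phenotype), X0)
  h <- hstats[hstats$snp_id %in% snp_set, , drop = FALSE]
  h <- h[order(h$p, h$snp_id), , drop = FALSE]
  empty <- list(p_threshold = NA_real_, delta_r2 = 0, n_snps = 0L,
                snps = character(0),
                table = data.frame(p_threshold = grid, n_snps = 0L,
                                   delta_r2 = NA_real_, p = NA_real_))
  if (nrow(h) == 0) return(empty)
  D <- genotypes$dosages[match(ids, rownames(genotypes$dosages)),
                         h$snp_id, drop = FALSE]
  storage.mode(D) <- "double"
  D[is.na(D)] <- 0
  ts <- .threshold_scores(D, h$beta, h$p, grid)
  if (is.null(ts$S)) return(empty)
  scr <- .screen_scores(ts$S, ctx, test = "anova")
  tab <- data.frame(p_threshold = grid, n_snps = ts$counts,
                    delta_r2 = NA_real_, p = NA_real_)
  hit <- match(ts$counts, ts$ucounts)
  ok <- !is.na(hit)
  tab$delta_r2[ok] <- scr$delta_r2[hit[ok]]
  tab$p[ok] <- scr$p[hit[ok]]
  best_u <- which.max(scr$delta_r2)
  best_count <- ts$ucounts[best_u]
  best_grid <- which(ts$counts == best_count)[1]  # most stringent equivalent
  list(p_threshold = grid[best_grid], delta_r2 = scr$delta_r2[best_u],
       adj_r2 = scr$adj_r2[best_u], anova_p = scr$p[best_u],
       n_snps = best_count, snps = h$snp_id[seq_len(best_count)],
       table = tab)
}
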