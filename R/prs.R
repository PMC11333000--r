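# Allelic scoring over SNP sets and p-value thresholds, the threshold
# grid, principal components and the coding-region covariate PRS.

#' Log-uniform p-value threshold grid
#'
#' `n` log-uniformly spaced thresholds spanning `[p_min, p_max]`,
#' endpoints included (defaults: 370 thresholds in `[1e-5, 1]`).
#'
#' @param n number of thresholds (>= 2).
#' @param p_min,p_max grid bounds, `0 < p_min < p_max <= 1`.
#' @return strictly increasing numeric vector of length `n`.
#' @export
threshold_grid <- function(n = 370, p_min = 1e-5, p_max = 1.0) {
  if (!is_count(n, min = 2)) stopf("threshold grid needs at least 2 values")
  if (!(p_min > 0 && p_min < p_max && p_max <= 1)) {
    stopf("need 0 < p_min < p_max <= 1")
  }
  g <- exp(seq(log(p_min), log(p_max), length.out = n))
  g[1] <- p_min
  g[n] <- p_max
  g
}

#' Harmonize summary statistics to a genotype panel
#'
#' Matches SNPs by id and aligns effect alleles to the panel's counted
#' allele: an exact allele match keeps the record, a swapped match flips
#' the sign of beta, strand-ambiguous SNPs (A/T or C/G pairs) and
#' irreconcilable allele pairs are dropped with logged counts.  When the
#' summary statistics carry no second allele (scoring dialect), matching
#' uses the effect allele alone.
#'
#' @param stats a [sumstats].
#' @param genotypes a [geno_matrix].
#' @return data.frame `snp_id`, `beta`, `p` for usable SNPs, with counts
#'   in attributes `flipped`, `dropped_ambiguous`, `dropped_mismatch`.
#' @export
harmonize_sumstats <- function(stats, genotypes) {
  gi <- match(stats$snp_id, genotypes$snps$snp_id)
  keep <- !is.na(gi)
  st <- stats[keep, , drop = FALSE]
  gs <- genotypes$snps[gi[keep], , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- !is.na(st$a2) & st$a2 == comp[st$a1]
  beta <- st$beta
  if (all(is.na(st$a2))) {
    same <- st$a1 == gs$a1
    flip <- st$a1 == gs$a2
    ambiguous <- rep(FALSE, nrow(st))
  } else {
    same <- st$a1 == gs$a1 & st$a2 == gs$a2
    flip <- st$a1 == gs$a2 & st$a2 == gs$a1
  }
  beta[flip] <- -beta[flip]
  use <- (same | flip) & !ambiguous
  n_amb <- sum(ambiguous & (same | flip))
  n_mis <- sum(!(same | flip))
  if (n_amb) titr_log("harmonize: dropped %d strand-ambiguous SNP(s)", n_amb)
  if (n_mis) titr_log("harmonize: dropped %d allele-mismatched SNP(s)", n_mis)
  out <- data.frame(snp_id = st$snp_id[use], beta = beta[use], p = st$p[use],
                    stringsAsFactors = FALSE)
  attr(out, "flipped") <- sum(flip & use)
  attr(out, "dropped_ambiguous") <- n_amb
  attr(out, "dropped_mismatch") <- n_mis
  out
}

#' Compute a polygenic risk score profile
#'
#' `score_i = sum over selected SNPs with p <= p_threshold of
#' beta * dosage_i`.  A missing dosage contributes exactly 0 (the
#' no-mean-imputation rule); alleles are harmonized to the panel's
#' counted allele first.  SNPs absent from the genotypes are dropped with
#' a logged count.
#'
#' @param genotypes cohort [geno_matrix].
#' @param stats [sumstats] supplying betas and p-values.
#' @param snps SNP ids eligible for scoring (default: all of `stats`).
#' @param p_threshold p-value ceiling (default 1).
#' @param label free-text provenance label.
#' @return object of class `prs_profile`: data.frame `sample_id`, `score`
#'   with attributes `snp_count`, `p_threshold`, `provenance`, `snps`.
#' @export
compute_prs <- function(genotypes, stats, snps = NULL, p_threshold = 1.0,
                        label = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(stats, "sumstats"))
  snps <- snps %||% stats$snp_id
  absent <- setdiff(intersect(snps, stats$snp_id), genotypes$snps$snp_id)
  if (length(absent)) titr_log("compute_prs: %d SNP(s) absent from genotypes",
                               length(absent))
  h <- harmonize_sumstats(stats, genotypes)
  h <- h[h$snp_id %in% snps & !is.na(h$p) & h$p <= p_threshold, ,
         drop = FALSE]
  n <- nrow(genotypes$dosages)
  score <- numeric(n)
  if (nrow(h)) {
    D <- genotypes$dosages[, h$snp_id, drop = FALSE]
    storage.mode(D) <- "double"
    D[is.na(D)] <- 0
    score <- as.vector(D %*% h$beta)
  }
  out <- data.frame(sample_id = rownames(genotypes$dosages), score = score,
                    stringsAsFactors = FALSE)
  attr(out, "snp_count") <- nrow(h)
  attr(out, "p_threshold") <- p_threshold
  attr(out, "provenance") <- label
  attr(out, "snps") <- h$snp_id
  class(out) <- c("prs_profile", "data.frame")
  out
}

#' Write a score profile
#'
#' `.sscore`-like table: `sample_id`, `score`, `snp_count`.
#' @param profile a `prs_profile`.
#' @param path output path.
#' @export
write_prs <- function(profile, path) {
  df <- data.frame(sample_id = profile$sample_id, score = profile$score,
                   snp_count = attr(profile, "snp_count"))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Principal components of a genotype matrix
#'
#' Top-`k` left singular directions of the column-standardized dosage
#' matrix (missing calls are mean-imputed for the PCA only).  A
#' deterministic sign convention (the largest-magnitude SNP loading of
#' each component is positive) makes repeated runs identical.  Small
#' problems use an exact decomposition; larger ones a deterministic
#' randomized subspace iteration.
#'
#' @param genotypes a [geno_matrix] with at least `k + 1` samples.
#' @param k number of components (default 10).
#' @return data.frame `sample_id`, `pc1` .. `pck` (component scores).
#' @export
compute_pcs <- function(genotypes, k = 10) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  X <- genotypes$dosages
  storage.mode(X) <- "double"
  n <- nrow(X)
  m <- ncol(X)
  if (k >= min(n, m)) stopf("k must be smaller than both matrix dimensions")
  if (n < k + 1) stopf("need at least k + 1 = %d samples", k + 1)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  mu <- colMeans(X)
  # standardize in chunks to avoid transient full-matrix copies
  for (js in seq(1, m, by = 2000)) {
    cols <- js:min(js + 1999, m)
    xc <- sweep(X[, cols, drop = FALSE], 2, mu[cols], "-")
    sdv <- sqrt(colSums(xc^2) / (n - 1))
    sdv[sdv == 0] <- Inf
    X[, cols] <- sweep(xc, 2, sdv, "/")
  }
  if (min(n, m) <= 600) {
    sv <- svd(X, nu = k, nv = k)
    U <- sv$u
    d <- sv$d[seq_len(k)]
    V <- sv$v
  } else {
    # randomized subspace iteration with a fixed internal seed
    p <- min(k + 8, m)
    Omega <- local_seed(20260927, matrix(rnorm(m * p), m, p))
    Q <- qr.Q(qr(X %*% Omega))
    for (it in 1:6) Q <- qr.Q(qr(X %*% crossprod(X, Q)))
    B <- crossprod(Q, X)           # p x m
    sb <- svd(B, nu = k, nv = k)
    U <- Q %*% sb$u
    d <- sb$d[seq_len(k)]
    V <- sb$v
  }
  for (j in seq_len(k)) {
    flip <- sign(V[which.max(abs(V[, j])), j])
    if (flip < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  scores <- sweep(U[, seq_len(k), drop = FALSE], 2, d, "*")
  out <- data.frame(sample_id = rownames(genotypes$dosages),
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("pc", j)]] <- scores[, j]
  out
}

#' Build the coding-region covariate PRS
#'
#' A standard pruning-and-thresholding model restricted to a user-supplied
#' (or simulator-flagged) coding SNP mask: one representative per LD block
#' is sampled from the mask, then the threshold-grid value maximizing the
#' adjusted-R^2 gain over the age/sex/PC covariates in the training cohort
#' is selected.  The optimized score is intended as the `coding_prs`
#' column of the null-model covariates, separating coding from regulatory
#' signal.
#'
#' @param genotypes training cohort [geno_matrix].
#' @param stats [sumstats].
#' @param coding_snps character vector of coding SNP ids.
#' @param phenotype named training phenotype vector.
#' @param covariates training covariate data.frame (any `coding_prs`
#'   column is ignored while optimizing).
#' @param clumps `clump_result` for the GWAS (training-population panel).
#' @param target_genotypes optional target cohort; when given, the
#'   optimized profile is returned for it too.
#' @param grid threshold grid (default [threshold_grid()]).
#' @return list with `train` (and optionally `target`) `prs_profile`s,
#'   the chosen `p_threshold`, `delta_r2_train`, and the selected `snps`.
#' @export
build_coding_covariate <- function(genotypes, stats, coding_snps, phenotype,
                                   covariates, clumps,
                                   target_genotypes = NULL,
                                   grid = threshold_grid()) {
  covariates <- covariates[, setdiff(names(covariates), "coding_prs"),
                           drop = FALSE]
  h <- harmonize_sumstats(stats, genotypes)
  coding_snps <- intersect(coding_snps, h$snp_id)
  zero_profile <- function(geno) {
    out <- data.frame(sample_id = rownames(geno$dosages), score = 0)
    attr(out, "snp_count") <- 0L
    attr(out, "p_threshold") <- NA_real_
    attr(out, "provenance") <- "coding"
    attr(out, "snps") <- character(0)
    class(out) <- c("prs_profile", "data.frame")
    out
  }
  if (length(coding_snps) == 0) {
    warning("empty coding SNP set; returning zero-score coding profile")
    out <- list(train = zero_profile(genotypes), p_threshold = NA_real_,
                delta_r2_train = 0, snps = character(0))
    if (!is.null(target_genotypes)) out$target <- zero_profile(target_genotypes)
    return(out)
  }
  sel <- block_sample(clumps, coding_snps)
  opt <- .pt_optimize(genotypes, h, sel, phenotype, covariates, grid)
  if (opt$n_snps == 0) {
    warning("no coding SNP passes any threshold; zero-score coding profile")
    out <- list(train = zero_profile(genotypes), p_threshold = NA_real_,
                delta_r2_train = 0, snps = character(0))
    if (!is.null(target_genotypes)) out$target <- zero_profile(target_genotypes)
    return(out)
  }
  out <- list(train = compute_prs(genotypes, stats, opt$snps,
                                  opt$p_threshold, "coding"),
              p_threshold = opt$p_threshold,
              delta_r2_train = opt$delta_r2, snps = opt$snps)
  if (!is.null(target_genotypes)) {
    out$target <- compute_prs(target_genotypes, stats, opt$snps,
                              opt$p_threshold, "coding")
  }
  out
}
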