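# LD-score computation and stratified LD score regression (S-LDSC).
#
# chi2_j is regressed on N_j * ell(j, C) across annotations C with a free
# intercept; heteroskedasticity weights come from a two-step scheme (an
# unweighted pass predicts chi2, the weighted pass uses
# 1 / (max(ell_base, 1) * pred^2)).  Standard errors are delete-one block
# jackknife over contiguous SNP blocks.  The standardized effect tau* of
# an annotation is the proportional change in per-SNP heritability per one
# standard deviation of annotation value: tau * sd(a) * M / h2_total.

#' Compute annotation-stratified LD scores
#'
#' `ell(j, C) = sum over SNPs k within the physical window of j (including
#' j itself) of a_C(k) * r2(j, k)`, with `r2` the squared Pearson
#' correlation of dosages over pairwise-complete samples.  Monomorphic
#' SNPs contribute r2 = 0 (logged).
#'
#' @param panel LD reference [geno_matrix] (>= 2 samples).
#' @param annotations numeric matrix, SNPs x annotations, row-aligned to
#'   the panel's SNPs; an all-ones `base` column is prepended when absent.
#' @param window_kb one-sided physical window in kb (default 1000).
#' @param chunk_size SNPs per block in the windowed pass.
#' @return object of class `ldscore_table`: list with `snp_id`, `ell`
#'   (SNP x annotation matrix), `annot`, `window_kb`, `chr`, `pos`.
#' @export
compute_ld_scores <- function(panel, annotations = NULL, window_kb = 1000,
                              chunk_size = 512) {
  stopifnot(inherits(panel, "geno_matrix"))
  n <- nrow(panel$dosages)
  if (n < 2) stopf("LD panel needs at least 2 samples")
  m <- ncol(panel$dosages)
  if (is.null(annotations)) {
    annotations <- matrix(1, m, 1, dimnames = list(panel$snps$snp_id, "base"))
  }
  annotations <- as.matrix(annotations)
  if (nrow(annotations) != m) {
    stopf("annotation matrix rows (%d) must match panel SNPs (%d)",
          nrow(annotations), m)
  }
  if (is.null(colnames(annotations))) {
    colnames(annotations) <- paste0("annot", seq_len(ncol(annotations)))
  }
  if (!any(apply(annotations, 2, function(x) all(x == 1)))) {
    annotations <- cbind(base = 1, annotations)
  }
  ord <- order(panel$snps$chr, panel$snps$pos)
  snps <- panel$snps[ord, , drop = FALSE]
  A <- annotations[ord, , drop = FALSE]
  X <- panel$dosages[, ord, drop = FALSE]
  storage.mode(X) <- "double"
  has_na <- anyNA(X)
  Xraw <- if (has_na) X else NULL   # sorted copy for pairwise-complete cor
  mono <- 0L
  if (!has_na) {
    mu <- colMeans(X)
    sdv <- sqrt(colSums(sweep(X, 2, mu, "-")^2) / (n - 1))
    mono <- sum(sdv == 0)
    sdv[sdv == 0] <- Inf  # standardized column becomes 0 -> r2 = 0
    X <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  }
  ell <- matrix(0, m, ncol(A), dimnames = list(snps$snp_id, colnames(A)))
  win <- window_kb * 1000
  for (ch in unique(snps$chr)) {
    idx <- which(snps$chr == ch)
    pos <- snps$pos[idx]
    for (s in seq(1, length(idx), by = chunk_size)) {
      ii <- idx[s:min(s + chunk_size - 1, length(idx))]
      pii <- snps$pos[ii]
      lo <- findInterval(min(pii) - win, pos) + 1L
      hi <- findInterval(max(pii) + win, pos)
      ee <- idx[lo:hi]
      if (has_na) {
        R <- suppressWarnings(cor(Xraw[, ii, drop = FALSE],
                                  Xraw[, ee, drop = FALSE],
                                  use = "pairwise.complete.obs"))
        R[is.na(R)] <- 0
      } else {
        R <- crossprod(X[, ii, drop = FALSE], X[, ee, drop = FALSE]) / (n - 1)
      }
      R2 <- R * R
      dist <- abs(outer(pii, snps$pos[ee], "-"))
      R2[dist > win] <- 0
      ell[ii, ] <- R2 %*% A[ee, , drop = FALSE]
    }
  }
  if (has_na) {
    frq <- colMeans(Xraw, na.rm = TRUE) / 2
    mono <- sum(frq == 0 | frq == 1)
  }
  if (mono > 0) titr_log("compute_ld_scores: %d monomorphic SNP(s), r2 set to 0",
                         mono)
  structure(list(snp_id = snps$snp_id, ell = ell, annot = A,
                 window_kb = window_kb, chr = snps$chr, pos = snps$pos),
            class = "ldscore_table")
}

# restrict an ldscore_table to a subset of annotation columns
subset_ld_scores <- function(lds, cols) {
  lds$ell <- lds$ell[, cols, drop = FALSE]
  lds$annot <- lds$annot[, cols, drop = FALSE]
  lds
}

#' Fit stratified LD score regression
#'
#' Weighted least squares of per-SNP chi-square statistics on
#' `N * ell(., C)` with a free intercept.  Returns per-annotation tau,
#' block-jackknife standard errors, standardized effects tau* with
#' two-sided normal p-values, heritability proportions and enrichment.
#'
#' @param stats [sumstats] with `chi2` and `n_eff` populated (apply any
#'   MAF filtering before calling).
#' @param lds an `ldscore_table` from [compute_ld_scores()].
#' @param n_blocks jackknife blocks (default 200, reduced to `floor(M/50)`
#'   with a log message when the SNP overlap is small).
#' @param focal name of the focal annotation column reported by
#'   [select_candidates()]; defaults to the last column.
#' @return object of class `sldsc_fit`: list with `table` (one row per
#'   annotation: `tau`, `tau_se`, `tau_star`, `tau_star_p`, `enrichment`
#'   with its block-jackknife `enrichment_se`, `prop_h2`), `h2_total`,
#'   `intercept`, `n_blocks`, `m`, `focal`,
#'   `annot`, `tau`, `h2_snp`.
#' @export
fit_sldsc <- function(stats, lds, n_blocks = 200, focal = NULL) {
  stopifnot(inherits(stats, "sumstats"), inherits(lds, "ldscore_table"))
  idx <- match(lds$snp_id, stats$snp_id)
  keep <- which(!is.na(idx))
  m <- length(keep)
  A <- lds$annot[keep, , drop = FALSE]
  if (m < ncol(A) + 2) stopf("too few overlapping SNPs (%d) to fit %d annotations",
                             m, ncol(A))
  st <- stats[idx[keep], , drop = FALSE]
  if (anyNA(st$chi2) || anyNA(st$n_eff)) {
    stopf("fit_sldsc requires chi2 and n_eff for every overlapping SNP")
  }
  ell <- lds$ell[keep, , drop = FALSE]
  Xr <- ell * st$n_eff           # recycles N down columns
  X <- cbind(`(intercept)` = 1, Xr)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("collinear annotation column(s): %s", paste(bad, collapse = ", "))
  }
  y <- st$chi2
  # step 1: unweighted pass for heteroskedasticity weights
  b0 <- qr.coef(qx, y)
  # predicted chi2 cannot drop below 1 under the model; flooring keeps the
  # inverse-variance weights bounded
  pred <- pmax(as.vector(X %*% b0), 1)
  base_col <- which(apply(A, 2, function(x) all(x == 1)))[1]
  ell_base <- if (!is.na(base_col)) ell[, base_col] else rowSums(ell)
  w <- 1 / (pmax(ell_base, 1) * pred^2)
  # step 2: weighted fit
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  G <- crossprod(Xw)
  cvec <- crossprod(Xw, yw)
  theta <- solve(G, cvec)
  # delete-one block jackknife over contiguous SNP blocks
  nb <- max(2L, min(as.integer(n_blocks), floor(m / 50)))
  if (nb < n_blocks) titr_log("fit_sldsc: jackknife blocks reduced to %d", nb)
  bnd <- floor(seq(0, m, length.out = nb + 1))
  theta_del <- matrix(0, nb, ncol(X))
  for (b in seq_len(nb)) {
    rows <- (bnd[b] + 1):bnd[b + 1]
    Gb <- crossprod(Xw[rows, , drop = FALSE])
    cb <- crossprod(Xw[rows, , drop = FALSE], yw[rows])
    theta_del[b, ] <- solve(G - Gb, cvec - cb)
  }
  th_bar <- colMeans(theta_del)
  se <- sqrt((nb - 1) / nb * colSums(sweep(theta_del, 2, th_bar, "-")^2))
  # jackknife pseudo-values for enrichment of each annotation
  member_mat <- (A != 0) + 0
  MA <- crossprod(member_mat, A)          # C x C
  colA <- colSums(A)
  prop_snps_v <- colMeans(member_mat)
  tau_del <- theta_del[, -1, drop = FALSE]
  h2_del <- as.vector(tau_del %*% colA)
  enr_del <- (tau_del %*% t(MA)) / h2_del /
    rep(prop_snps_v, each = nb)
  enr_bar <- colMeans(enr_del)
  enrichment_se <- sqrt((nb - 1) / nb *
                          colSums(sweep(enr_del, 2, enr_bar, "-")^2))
  tau <- as.vector(theta)[-1]
  tau_se <- se[-1]
  names(tau) <- names(tau_se) <- colnames(A)
  intercept <- as.vector(theta)[1]
  h2_snp <- as.vector(A %*% tau)
  h2_total <- sum(h2_snp)
  sd_a <- apply(A, 2, sd)
  tau_star <- ifelse(sd_a > 0 & h2_total != 0,
                     tau * sd_a * m / h2_total, ifelse(tau == 0, 0, NA))
  z <- ifelse(tau_se > 0, tau / tau_se,
              ifelse(tau == 0, 0, sign(tau) * Inf))
  tau_star_p <- 2 * pnorm(-abs(z))
  member <- A != 0
  prop_snps <- colMeans(member)
  prop_h2 <- if (h2_total != 0) {
    as.vector(crossprod(member, h2_snp)) / h2_total
  } else rep(NA_real_, ncol(A))
  enrichment <- ifelse(prop_snps > 0, prop_h2 / prop_snps, NA)
  tab <- data.frame(annotation = colnames(A), tau = tau, tau_se = tau_se,
                    tau_star = tau_star, tau_star_p = tau_star_p,
                    enrichment = enrichment, enrichment_se = enrichment_se,
                    prop_h2 = prop_h2, row.names = colnames(A))
  structure(list(table = tab, h2_total = h2_total, intercept = intercept,
                 n_blocks = nb, m = m,
                 focal = focal %||% colnames(A)[ncol(A)],
                 annot = A, tau = tau, h2_snp = h2_snp,
                 snp_id = lds$snp_id[keep]),
            class = "sldsc_fit")
}

#' @export
print.sldsc_fit <- function(x, ...) {
  cat(sprintf("sldsc_fit: %d SNPs, h2 = %.4g, intercept = %.3f (focal: %s)\n",
              x$m, x$h2_total, x$intercept, x$focal))
  print(x$table, digits = 4)
  invisible(x)
}

#' Proportion of heritability in a partition
#'
#' `sum over partition members of per-SNP h2` divided by total h2, with
#' per-SNP h2 from the fitted annotation model.
#'
#' @param fit an `sldsc_fit`.
#' @param partition an annotation column name (membership = non-zero
#'   value), a character vector of SNP ids, or a logical/0-1 vector over
#'   the fit's SNPs.
#' @return fraction (possibly outside `[0, 1]` through estimation noise).
#' @export
proportion_h2 <- function(fit, partition) {
  stopifnot(inherits(fit, "sldsc_fit"))
  if (fit$h2_total <= 0) stopf("total h2 estimate is not positive; proportion undefined")
  member <- if (is.character(partition) && length(partition) == 1 &&
                partition %in% colnames(fit$annot)) {
    fit$annot[, partition] != 0
  } else if (is.character(partition)) {
    fit$snp_id %in% partition
  } else if (is.logical(partition) || all(partition %in% c(0, 1))) {
    as.logical(partition)
  } else {
    stopf("unrecognized partition specification")
  }
  if (length(member) != fit$m) stopf("partition length does not match fit")
  sum(fit$h2_snp[member]) / fit$h2_total
}

#' Select candidate tissues by standardized effect size
#'
#' The gate used on each refinement iteration: keep tissues with
#' `tau* > 0` and `p(tau*) < 0.05 / n_tissues` (Bonferroni over the tissue
#' models tested), ordered by descending tau*.
#'
#' @param fits named list of `sldsc_fit`s (one per tissue; the focal
#'   annotation's row is used), or a data.frame with columns `tissue`,
#'   `tau_star`, `tau_star_p`.
#' @param n_tissues Bonferroni denominator (defaults to the number of
#'   fits/rows, e.g. 51 for the full tissue catalogue).
#' @return character vector of selected tissues (possibly empty), with the
#'   per-tissue table attached as attribute `"table"`.
#' @export
select_candidates <- function(fits, n_tissues = NULL) {
  if (is.data.frame(fits)) {
    tab <- data.frame(tissue = fits$tissue, tau_star = fits$tau_star,
                      tau_star_p = fits$tau_star_p)
  } else {
    tab <- do.call(rbind, lapply(names(fits), function(ts) {
      row <- fits[[ts]]$table[fits[[ts]]$focal, ]
      data.frame(tissue = ts, tau_star = row$tau_star,
                 tau_star_p = row$tau_star_p)
    }))
  }
  n_tissues <- n_tissues %||% nrow(tab)
  alpha <- 0.05 / n_tissues
  sel <- !is.na(tab$tau_star) & tab$tau_star > 0 &
    !is.na(tab$tau_star_p) & tab$tau_star_p < alpha
  out <- tab$tissue[sel][order(-tab$tau_star[sel])]
  attr(out, "table") <- tab
  attr(out, "alpha") <- alpha
  out
}

#' Write an LD score table or S-LDSC fit to disk
#'
#' @param x an `ldscore_table` or `sldsc_fit`.
#' @param path output path (tab-delimited).
#' @export
write_ldsc <- function(x, path) {
  if (inherits(x, "ldscore_table")) {
    df <- data.frame(snp_id = x$snp_id, chr = x$chr, pos = x$pos)
    df <- cbind(df, as.data.frame(x$ell))
  } else if (inherits(x, "sldsc_fit")) {
    df <- x$table
  } else stopf("unsupported object")
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
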