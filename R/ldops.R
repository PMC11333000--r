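# Greedy p-value clumping (PLINK-style) and the LD-block sampling rule
# that admits at most one SNP per block into the PRS model.

#' Greedy p-value clumping
#'
#' PLINK-style algorithm: SNPs are sorted by ascending GWAS p-value (ties
#' broken by position then snp_id); the best unassigned SNP becomes an
#' index variant and absorbs every unassigned SNP within the physical
#' window whose dosage r-squared with it reaches the threshold.  SNPs with
#' `p > p_ceiling` may be absorbed but never become indexes; any left
#' unabsorbed, and monomorphic SNPs, end up `unassigned`.
#'
#' @param stats [sumstats] with p-values.
#' @param panel LD reference [geno_matrix]; the intersection of its SNPs
#'   with `stats` is clumped (logged if rows are dropped).
#' @param r2_threshold squared-correlation threshold (default 0.2).
#' @param window_kb one-sided physical window in kb (default 250).
#' @param p_ceiling maximum index p-value (default 1, i.e. no ceiling).
#' @return object of class `clump_result`: list with `blocks` (each a
#'   list `index_snp`, `members` sorted by ascending p), `assign`
#'   (data.frame snp_id/block/is_index/p), `unassigned`, `r2_threshold`,
#'   `window_kb` and the p-value lookup `p`.
#' @export
clump <- function(stats, panel, r2_threshold = 0.2, window_kb = 250,
                  p_ceiling = 1.0) {
  stopifnot(inherits(stats, "sumstats"), inherits(panel, "geno_matrix"))
  common <- intersect(stats$snp_id, panel$snps$snp_id)
  if (length(common) == 0) stopf("no SNP shared between summary statistics and panel")
  dropped <- length(stats$snp_id) - length(common)
  if (dropped > 0) titr_log("clump: %d summary-stat SNP(s) absent from panel",
                            dropped)
  si <- match(common, stats$snp_id)
  gi <- match(common, panel$snps$snp_id)
  df <- data.frame(snp_id = common, p = stats$p[si],
                   chr = panel$snps$chr[gi], pos = panel$snps$pos[gi],
                   col = gi, stringsAsFactors = FALSE)
  D <- panel$dosages
  frq <- colMeans(D, na.rm = TRUE) / 2
  mono <- df$snp_id[frq[df$col] %in% c(0, 1)]
  df <- df[!df$snp_id %in% mono, , drop = FALSE]
  ord <- order(df$p, df$chr, df$pos, df$snp_id)
  df <- df[ord, , drop = FALSE]
  win <- window_kb * 1000
  n <- nrow(df)
  remaining <- rep(TRUE, n)
  eligible <- df$p <= p_ceiling
  blocks <- list()
  Dd <- D[, df$col, drop = FALSE]
  storage.mode(Dd) <- "double"
  has_na <- anyNA(Dd)
  if (!has_na) {
    # pre-standardize so per-index correlations reduce to crossproducts
    ns <- nrow(Dd)
    mu <- colMeans(Dd)
    sdv <- sqrt(colSums(sweep(Dd, 2, mu, "-")^2) / (ns - 1))
    sdv[sdv == 0] <- Inf
    Dd <- sweep(sweep(Dd, 2, mu, "-"), 2, sdv, "/")
  }
  # physical window candidates, by position order within chromosome
  pord <- order(df$chr, df$pos)
  rankpos <- integer(n)
  rankpos[pord] <- seq_len(n)
  next_eligible <- 1L
  repeat {
    while (next_eligible <= n &&
           (!remaining[next_eligible] || !eligible[next_eligible])) {
      next_eligible <- next_eligible + 1L
    }
    if (next_eligible > n) break
    i <- next_eligible
    # walk outwards in position order while inside the window
    r0 <- rankpos[i]
    lo <- r0
    while (lo > 1 && df$chr[pord[lo - 1]] == df$chr[i] &&
           df$pos[i] - df$pos[pord[lo - 1]] <= win) lo <- lo - 1
    hi <- r0
    while (hi < n && df$chr[pord[hi + 1]] == df$chr[i] &&
           df$pos[pord[hi + 1]] - df$pos[i] <= win) hi <- hi + 1
    cand <- pord[lo:hi]
    cand <- cand[remaining[cand] & cand != i]
    mem <- integer(0)
    if (length(cand)) {
      r <- if (has_na) {
        suppressWarnings(as.vector(cor(Dd[, i], Dd[, cand, drop = FALSE],
                                       use = "pairwise.complete.obs")))
      } else {
        as.vector(crossprod(Dd[, i], Dd[, cand, drop = FALSE])) / (nrow(Dd) - 1)
      }
      r[is.na(r)] <- 0
      mem <- cand[r * r >= r2_threshold]
      mem <- mem[order(df$p[mem], df$snp_id[mem])]
    }
    blocks[[length(blocks) + 1]] <- list(index_snp = df$snp_id[i],
                                         members = df$snp_id[mem])
    remaining[c(i, mem)] <- FALSE
  }
  unassigned <- c(mono, df$snp_id[remaining])
  assign <- data.frame(
    snp_id = unlist(lapply(blocks, function(b) c(b$index_snp, b$members))),
    block = rep(seq_along(blocks),
                vapply(blocks, function(b) 1L + length(b$members), 1L)),
    is_index = unlist(lapply(blocks,
                             function(b) c(TRUE, rep(FALSE, length(b$members))))),
    stringsAsFactors = FALSE)
  pmap <- setNames(stats$p[match(c(df$snp_id, mono),
                                 stats$snp_id)], c(df$snp_id, mono))
  assign$p <- pmap[assign$snp_id]
  out <- structure(list(blocks = blocks, assign = assign,
                        unassigned = unassigned,
                        r2_threshold = r2_threshold, window_kb = window_kb,
                        p = pmap),
                   class = "clump_result")
  attr(out, "universe") <- clump_universe(out)
  out
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("clump_result: %d blocks (r2 >= %g, window %g kb), %d unassigned\n",
              length(x$blocks), x$r2_threshold, x$window_kb,
              length(x$unassigned)))
  invisible(x)
}

#' Write a clump table
#'
#' PLINK `--clump`-like output: index SNP, its p-value and the
#' comma-separated member list.
#' @param clumps a `clump_result`.
#' @param path output path.
#' @export
write_clumps <- function(clumps, path) {
  df <- data.frame(
    index_snp = vapply(clumps$blocks, `[[`, character(1), "index_snp"),
    p = clumps$p[vapply(clumps$blocks, `[[`, character(1), "index_snp")],
    members = vapply(clumps$blocks, function(b) {
      if (length(b$members)) paste(b$members, collapse = ",") else "."
    }, character(1)))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Sample at most one SNP per LD block from a partition
#'
#' For every block that intersects the partition, the block's index
#' variant is selected when it belongs to the partition, otherwise the
#' partition member with the smallest GWAS p-value (ties broken by
#' snp_id).  Blocks containing any already-selected SNP are saturated and
#' contribute nothing, which enforces the one-SNP-per-block rule across
#' refinement iterations, not merely within one call.  Unassigned SNPs are
#' treated as singleton blocks.  Only the new selections are returned; the
#' caller merges them with the running model.
#'
#' @param clumps a `clump_result`.
#' @param partition a [partition] or character vector of SNP ids.
#' @param already_selected SNPs already in the model (saturates blocks).
#' @return character vector of newly selected SNP ids.
#' @export
block_sample <- function(clumps, partition, already_selected = character()) {
  stopifnot(inherits(clumps, "clump_result"))
  part <- if (inherits(partition, "partition")) partition$snp_ids else
    as.character(partition)
  part <- unique(part)
  u <- clump_universe(clumps)
  in_part <- u$snp_id %in% part
  saturated <- u$block %in% u$block[u$snp_id %in% already_selected]
  cand <- u[in_part & !saturated, , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  # index variant first, then smallest GWAS p, then snp_id
  cand <- cand[order(cand$block, !cand$is_index, cand$p, cand$snp_id), ,
               drop = FALSE]
  cand$snp_id[!duplicated(cand$block)]
}

# flattened block membership with unassigned SNPs as singleton blocks
clump_universe <- function(clumps) {
  u <- attr(clumps, "universe")
  if (!is.null(u)) return(u)
  a <- clumps$assign
  if (length(clumps$unassigned)) {
    a <- rbind(a, data.frame(
      snp_id = clumps$unassigned,
      block = max(a$block, 0L) + seq_along(clumps$unassigned),
      is_index = TRUE,
      p = unname(clumps$p[clumps$unassigned])))
  }
  a
}
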