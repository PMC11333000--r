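# Domain containers and text-format readers/writers.
#
# Two whitespace-delimited summary-statistic dialects are supported:
#   * "heritability": SNP, A1, A2, N, CHISQ  (per-SNP chi-square and
#     effective sample size, the inputs heritability partitioning needs)
#   * "scoring":      SNP, A1, BETA, P       (effect sizes and association
#     p-values, the inputs allelic scoring needs)
# Optional columns CHR, BP, A2, SE, MAF are carried through when present.

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics table
#'
#' A `sumstats` object is a data.frame with one row per SNP and columns
#' `snp_id`, `chr`, `pos`, `a1` (effect allele), `a2`, `beta`, `se`,
#' `p`, `chi2`, `n_eff` and `maf`.  Missing optional fields are `NA`.
#' The chi-square and p-value views are kept mutually consistent under a
#' 1-df chi-square: `p = P(chi2_1 > chi2)`.
#'
#' @param df data.frame with at least `snp_id` and `a1`; other recognized
#'   columns: `chr`, `pos`, `a2`, `beta`, `se`, `p`, `chi2`, `n_eff`, `maf`.
#' @return object of class `sumstats`.
#' @export
sumstats <- function(df) {
  stopifnot(is.data.frame(df), "snp_id" %in% names(df), "a1" %in% names(df))
  full <- c("snp_id", "chr", "pos", "a1", "a2", "beta", "se", "p", "chi2",
            "n_eff", "maf")
  out <- data.frame(snp_id = as.character(df$snp_id), stringsAsFactors = FALSE)
  for (col in full[-1]) {
    out[[col]] <- if (col %in% names(df)) df[[col]] else NA
  }
  out$a1 <- toupper(as.character(out$a1))
  if (!all(is.na(out$a2))) out$a2 <- toupper(as.character(out$a2))
  # back-fill the missing view
  need_chi2 <- is.na(out$chi2) & !is.na(out$p)
  out$chi2[need_chi2] <- qchisq(out$p[need_chi2], df = 1, lower.tail = FALSE)
  need_p <- is.na(out$p) & !is.na(out$chi2)
  out$p[need_p] <- pchisq(out$chi2[need_p], df = 1, lower.tail = FALSE)
  validate_sumstats(out)
  class(out) <- c("sumstats", "data.frame")
  out
}

validate_sumstats <- function(x) {
  dup <- duplicated(x$snp_id)
  if (any(dup)) {
    stopf("duplicate snp_id in summary statistics (first: '%s')",
          x$snp_id[which(dup)[1]])
  }
  if (any(!is.na(x$chi2) & x$chi2 < 0)) stopf("negative chi2 value")
  bad_p <- !is.na(x$p) & (x$p <= 0 | x$p > 1)
  if (any(bad_p)) stopf("p-value outside (0, 1] for snp '%s'",
                        x$snp_id[which(bad_p)[1]])
  both <- !is.na(x$p) & !is.na(x$chi2)
  if (any(both)) {
    ref <- pchisq(x$chi2[both], df = 1, lower.tail = FALSE)
    if (max(abs(ref - x$p[both])) >= 1e-8) {
      stopf("p and chi2 views disagree beyond 1e-8 (snp '%s')",
            x$snp_id[both][which.max(abs(ref - x$p[both]))])
    }
  }
  invisible(x)
}

DIALECT_COLUMNS <- list(
  heritability = c("SNP", "A1", "A2", "N", "CHISQ"),
  scoring      = c("SNP", "A1", "BETA", "P")
)

#' Read GWAS summary statistics
#'
#' Parses whitespace/tab-delimited summary statistics in one of the two
#' supported dialects.  Rows with unparseable alleles or with p-values
#' outside `(0, 1]` are dropped with a logged count; the absent view
#' (`chi2` or `p`) is back-filled from the present one.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect `"scoring"` (columns SNP, A1, BETA, P) or
#'   `"heritability"` (columns SNP, A1, A2, N, CHISQ; `Z` accepted as an
#'   alias for `CHISQ`).
#' @return a [sumstats] object.
#' @export
read_sumstats <- function(path, dialect = c("scoring", "heritability")) {
  dialect <- match.arg(dialect)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  names(dt) <- toupper(names(dt))
  if (dialect == "heritability" && !"CHISQ" %in% names(dt) && "Z" %in% names(dt)) {
    names(dt)[names(dt) == "Z"] <- "CHISQ"
  }
  for (col in DIALECT_COLUMNS[[dialect]]) {
    if (!col %in% names(dt)) {
      stopf("summary statistics file '%s' is missing mandatory column '%s'",
            path, col)
    }
  }
  dup <- duplicated(dt$SNP)
  if (any(dup)) {
    stopf("duplicate snp_id '%s' in '%s'", dt$SNP[which(dup)[1]], path)
  }
  n0 <- nrow(dt)
  ok <- toupper(dt$A1) %in% VALID_ALLELES
  if ("A2" %in% names(dt)) ok <- ok & toupper(dt$A2) %in% VALID_ALLELES
  if ("P" %in% names(dt)) ok <- ok & !is.na(dt$P) & dt$P > 0 & dt$P <= 1
  if ("CHISQ" %in% names(dt)) ok <- ok & !is.na(dt$CHISQ) & dt$CHISQ >= 0
  dt <- dt[ok, , drop = FALSE]
  if (nrow(dt) < n0) {
    titr_log("read_sumstats: dropped %d of %d rows (bad alleles or p outside (0,1])",
             n0 - nrow(dt), n0)
  }
  df <- data.frame(snp_id = as.character(dt$SNP), a1 = dt$A1,
                   stringsAsFactors = FALSE)
  map <- c(chr = "CHR", pos = "BP", a2 = "A2", beta = "BETA", se = "SE",
           p = "P", chi2 = "CHISQ", n_eff = "N", maf = "MAF")
  for (k in names(map)) if (map[[k]] %in% names(dt)) df[[k]] <- dt[[map[[k]]]]
  sumstats(df)
}

#' Write GWAS summary statistics
#'
#' @param stats a [sumstats] object.
#' @param path output path.
#' @param dialect which column dialect to emit (see [read_sumstats]);
#'   optional columns (`CHR`, `BP`, `A2`, `MAF`) present in `stats` are
#'   appended after the mandatory ones.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path, dialect = c("scoring", "heritability")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(stats, "sumstats"))
  if (dialect == "scoring") {
    out <- data.frame(SNP = stats$snp_id, A1 = stats$a1, BETA = stats$beta,
                      P = stats$p)
  } else {
    out <- data.frame(SNP = stats$snp_id, A1 = stats$a1, A2 = stats$a2,
                      N = stats$n_eff, CHISQ = stats$chi2)
  }
  extra <- c(CHR = "chr", BP = "pos", A2 = "a2", MAF = "maf")
  for (k in names(extra)) {
    v <- stats[[extra[[k]]]]
    if (!k %in% names(out) && !all(is.na(v))) out[[k]] <- v
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Genotype matrices

#' Construct a genotype dosage matrix
#'
#' Dosages count copies of each SNP's effect allele (`a1` in the variant
#' table) and take values in `{0, 1, 2, NA}`; `NA` marks a missing call and
#' is treated distinctly from 0 throughout (scoring never mean-imputes).
#'
#' @param dosages integer matrix, samples in rows, SNPs in columns;
#'   dimnames give sample and SNP ids.
#' @param snps data.frame with columns `snp_id`, `chr`, `pos`, `a1`, `a2`
#'   aligned with the columns of `dosages`.
#' @param population free-text population label.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, snps, population = "unknown") {
  stopifnot(is.matrix(dosages), is.data.frame(snps))
  req <- c("snp_id", "chr", "pos", "a1", "a2")
  miss <- setdiff(req, names(snps))
  if (length(miss)) stopf("variant table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (ncol(dosages) != nrow(snps)) {
    stopf("genotype matrix has %d SNP columns but variant table has %d rows",
          ncol(dosages), nrow(snps))
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("sample%05d", seq_len(nrow(dosages)))
  }
  colnames(dosages) <- snps$snp_id
  bad_allele <- !(toupper(snps$a1) %in% VALID_ALLELES &
                    toupper(snps$a2) %in% VALID_ALLELES)
  if (any(bad_allele)) stopf("unknown allele code for snp '%s'",
                             snps$snp_id[which(bad_allele)[1]])
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    stopf("dosages must be in {0, 1, 2, NA}")
  }
  structure(list(dosages = dosages,
                 snps = as.data.frame(snps, stringsAsFactors = FALSE),
                 population = population),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs (population: %s, %d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), x$population,
              sum(is.na(x$dosages))))
  invisible(x)
}

#' Effect-allele frequencies of a genotype matrix
#'
#' @param geno a [geno_matrix].
#' @return named numeric vector of per-SNP frequencies of the counted
#'   (`a1`) allele, computed over non-missing calls.
#' @export
allele_freq <- function(geno) {
  colMeans(geno$dosages, na.rm = TRUE) / 2
}

sample_ids <- function(geno) rownames(geno$dosages)

#' Read genotypes from disk
#'
#' Two formats are supported.  `dosage_text` is this package's plain-text
#' dialect: `<prefix>.dosage.tsv` holds a `sample_id` column followed by
#' one integer column per SNP (`NA` for missing calls), and
#' `<prefix>.snps.tsv` holds the variant table (`snp_id`, `chr`, `pos`,
#' `a1`, `a2`).  `plink_bed` reads a binary PLINK fileset
#' `<prefix>.bed/.bim/.fam` (SNP-major), counting the `.bim` A1 allele.
#'
#' @param prefix file prefix (no extension).
#' @param format `"dosage_text"` or `"plink_bed"`.
#' @param population population label to attach.
#' @return a [geno_matrix].
#' @export
read_genotypes <- function(prefix, format = c("dosage_text", "plink_bed"),
                           population = "unknown") {
  format <- match.arg(format)
  if (format == "plink_bed") return(read_plink_bed(prefix, population))
  dfile <- paste0(prefix, ".dosage.tsv")
  sfile <- paste0(prefix, ".snps.tsv")
  dt <- data.table::fread(dfile, header = TRUE, data.table = FALSE)
  snps <- data.table::fread(sfile, header = TRUE, data.table = FALSE)
  if (!identical(names(dt)[1], "sample_id")) {
    stopf("'%s' must start with a sample_id column", dfile)
  }
  if (!setequal(names(dt)[-1], snps$snp_id) ||
      ncol(dt) - 1L != nrow(snps)) {
    stopf("sample/SNP mismatch between '%s' and '%s'", dfile, sfile)
  }
  m <- as.matrix(dt[, snps$snp_id, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(dt$sample_id)
  geno_matrix(m, snps, population)
}

#' Write genotypes to disk
#'
#' @param geno a [geno_matrix].
#' @param prefix output prefix.
#' @param format see [read_genotypes].
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(geno, prefix, format = c("dosage_text", "plink_bed")) {
  format <- match.arg(format)
  if (format == "plink_bed") return(write_plink_bed(geno, prefix))
  d <- as.data.frame(geno$dosages)
  out <- cbind(data.frame(sample_id = rownames(geno$dosages)), d)
  data.table::fwrite(out, paste0(prefix, ".dosage.tsv"), sep = "\t",
                     quote = FALSE, na = "NA")
  data.table::fwrite(geno$snps, paste0(prefix, ".snps.tsv"), sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(prefix)
}

# ---------------------------------------------------------------------------
# Covariates

#' Read or write a covariate table
#'
#' Tab-delimited with a mandatory `sample_id` column; typical columns are
#' `age` (years), `sex` (0/1), `pc1`..`pc10` and `coding_prs`.
#'
#' @param path file path.
#' @return data.frame (for the reader).
#' @export
read_covariates <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!"sample_id" %in% names(df)) stopf("covariate file missing 'sample_id'")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' @rdname read_covariates
#' @param covariates data.frame to write.
#' @export
write_covariates <- function(covariates, path) {
  data.table::fwrite(covariates, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# ---------------------------------------------------------------------------
# TITR model log

#' Construct a TITR iteration log
#'
#' One row per accepted iteration plus, for each iteration, the list of
#' SNPs merged into the model at that iteration.
#'
#' @param entries data.frame with columns `iteration`, `tissue`, `bin`,
#'   `p_threshold`, `n_added`, `n_cumulative`, `delta_r2_train`,
#'   `selection_p`, `delta_r2_valid`.
#' @param snps list (one character vector per iteration) of newly added
#'   SNP ids.
#' @return object of class `titr_log`.
#' @export
titr_log_new <- function(entries, snps) {
  cols <- c("iteration", "tissue", "bin", "p_threshold", "n_added",
            "n_cumulative", "delta_r2_train", "selection_p", "delta_r2_valid")
  if (nrow(entries) == 0) {
    entries <- data.frame(iteration = integer(), tissue = character(),
                          bin = integer(), p_threshold = numeric(),
                          n_added = integer(), n_cumulative = integer(),
                          delta_r2_train = numeric(), selection_p = numeric(),
                          delta_r2_valid = numeric())
  }
  miss <- setdiff(cols, names(entries))
  for (m in miss) entries[[m]] <- NA
  entries <- entries[, cols]
  if (nrow(entries) && !identical(as.integer(entries$iteration),
                                  seq_len(nrow(entries)))) {
    stopf("log iterations must be 1..%d without gaps", nrow(entries))
  }
  if (length(snps) != nrow(entries)) {
    stopf("snp list length (%d) != number of log entries (%d)",
          length(snps), nrow(entries))
  }
  structure(list(entries = entries, snps = snps), class = "titr_log")
}

#' Write / read a TITR log
#'
#' The main file is tab-delimited with one row per iteration; a companion
#' `<path>.snps.tsv` lists the SNPs merged at each iteration
#' (`iteration`, `snp_id`).  Round-trips exactly.
#'
#' @param log a [titr_log_new] object.
#' @param path output path for the main log table.
#' @export
write_titr_log <- function(log, path) {
  stopifnot(inherits(log, "titr_log"))
  data.table::fwrite(log$entries, path, sep = "\t", quote = FALSE, na = "NA")
  snp_df <- if (length(log$snps)) {
    data.frame(iteration = rep(seq_along(log$snps), lengths(log$snps)),
               snp_id = unlist(log$snps, use.names = FALSE))
  } else data.frame(iteration = integer(), snp_id = character())
  data.table::fwrite(snp_df, paste0(path, ".snps.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_titr_log
#' @export
read_titr_log <- function(path) {
  entries <- data.table::fread(path, header = TRUE, data.table = FALSE)
  snp_df <- data.table::fread(paste0(path, ".snps.tsv"), header = TRUE,
                              data.table = FALSE,
                              colClasses = c(iteration = "integer",
                                             snp_id = "character"))
  k <- nrow(entries)
  snps <- lapply(seq_len(k), function(i) {
    as.character(snp_df$snp_id[snp_df$iteration == i])
  })
  if (k && !setequal(unique(snp_df$iteration), seq_len(k))) {
    if (length(setdiff(unique(snp_df$iteration), seq_len(k)))) {
      stopf("SNP list references iterations missing from the log")
    }
  }
  titr_log_new(entries, snps)
}

# ---------------------------------------------------------------------------
# Partitions

#' Construct an annotation partition
#'
#' A partition is a named subset of SNPs selected from one tissue's
#' annotation track, either the top fraction of the distribution or a
#' single percentile bin.
#'
#' @param tissue_label tissue the partition is drawn from.
#' @param selector list with `type` (`"top_fraction"` or `"bin"`) and
#'   `value` (the fraction or bin index).
#' @param snp_ids member SNP ids.
#' @return object of class `partition`.
#' @export
partition <- function(tissue_label, selector, snp_ids) {
  stopifnot(is.list(selector), selector$type %in% c("top_fraction", "bin"))
  structure(list(tissue_label = tissue_label, selector = selector,
                 snp_ids = as.character(snp_ids)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %s [%s = %s], %d SNPs\n", x$tissue_label,
              x$selector$type, format(x$selector$value), length(x$snp_ids)))
  invisible(x)
}

#' Write / read a partition file
#'
#' Tab-delimited: `tissue`, `selector_type`, `selector_value`, `snp_id`.
#' @param part a [partition].
#' @param path file path.
#' @export
write_partition <- function(part, path) {
  df <- data.frame(tissue = part$tissue_label,
                   selector_type = part$selector$type,
                   selector_value = part$selector$value,
                   snp_id = part$snp_ids)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  partition(df$tissue[1],
            list(type = df$selector_type[1], value = df$selector_value[1]),
            as.character(df$snp_id))
}
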