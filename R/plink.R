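# Minimal PLINK 1 binary fileset adapter (SNP-major .bed + .bim/.fam).
# Dosages count the .bim A1 allele: 2-bit codes 00 = hom A1 (dosage 2),
# 10 = het (1), 11 = hom A2 (0), 01 = missing.

read_plink_bed <- function(prefix, population = "unknown") {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stopf("PLINK fileset incomplete: '%s' not found", f)
  }
  bim_df <- data.table::fread(bim, header = FALSE, data.table = FALSE,
                              col.names = c("chr", "snp_id", "cm", "pos",
                                            "a1", "a2"))
  fam_df <- data.table::fread(fam, header = FALSE, data.table = FALSE)
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed, what = "raw", n = 3 + m * bytes_per_snp)
  if (length(raw) < 3 || !identical(as.integer(raw[1:3]),
                                    c(0x6cL, 0x1bL, 0x01L))) {
    stopf("'%s' is not a SNP-major PLINK .bed file", bed)
  }
  body <- raw[-(1:3)]
  if (length(body) != m * bytes_per_snp) {
    stopf("'%s': expected %d data bytes for %d samples x %d SNPs, found %d",
          bed, m * bytes_per_snp, n, m, length(body))
  }
  # decode 2-bit genotype codes, sample-fastest within a byte
  ints <- as.integer(body)
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = m)
  shift <- ints
  for (s in 1:4) {
    codes[seq(s, by = 4, length.out = bytes_per_snp), ] <- shift %% 4L
    shift <- shift %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2L, NA_integer_, 1L, 0L)  # codes 0,1,2,3
  dos <- matrix(lookup[codes + 1L], nrow = n, ncol = m)
  rownames(dos) <- as.character(fam_df[[2]])
  snps <- bim_df[, c("snp_id", "chr", "pos", "a1", "a2")]
  geno_matrix(dos, snps, population)
}

write_plink_bed <- function(geno, prefix) {
  dos <- geno$dosages
  n <- nrow(dos)
  m <- ncol(dos)
  bytes_per_snp <- ceiling(n / 4)
  # map dosage -> 2-bit code
  code <- matrix(1L, nrow = 4 * bytes_per_snp, ncol = m)  # pad with "missing"
  cmap <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  code[seq_len(n), ] <- cmap(dos)
  if (4 * bytes_per_snp > n) code[(n + 1):(4 * bytes_per_snp), ] <- 0L
  w <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, nrow = bytes_per_snp, ncol = m)
  for (s in 1:4) {
    bytes <- bytes + w[s] * code[seq(s, by = 4, length.out = bytes_per_snp), ,
                                 drop = FALSE]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  snps <- geno$snps
  bim <- data.frame(chr = snps$chr, snp_id = snps$snp_id, cm = 0,
                    pos = snps$pos, a1 = snps$a1, a2 = snps$a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  ids <- rownames(dos)
  fam <- data.frame(fid = ids, iid = ids, pat = 0, mat = 0, sex = 0,
                    phe = -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(prefix)
}
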