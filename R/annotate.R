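# Quantile normalization, percentile binning and partition extraction for
# tissue-specific annotation tracks.

#' Construct an annotation track
#'
#' One tissue model's continuous per-SNP regulatory scores.  `norm_score`
#' and `bin` start empty and are filled by [quantile_normalize()] and
#' [assign_bins()].
#'
#' @param tissue_label tissue name.
#' @param snp_id character vector of SNP ids.
#' @param raw_score numeric regulatory probabilities in `[0, 1]`.
#' @return object of class `annotation_track`.
#' @export
annotation_track <- function(tissue_label, snp_id, raw_score) {
  stopifnot(length(snp_id) == length(raw_score))
  if (anyDuplicated(snp_id)) stopf("duplicate snp_id in annotation track")
  structure(list(tissue_label = as.character(tissue_label),
                 snp_id = as.character(snp_id),
                 raw_score = as.numeric(raw_score),
                 norm_score = rep(NA_real_, length(snp_id)),
                 bin = rep(NA_integer_, length(snp_id))),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("annotation_track '%s': %d SNPs (normalized: %s, binned: %s)\n",
              x$tissue_label, length(x$snp_id),
              !anyNA(x$norm_score), !anyNA(x$bin)))
  invisible(x)
}

#' Quantile-normalize annotation tracks
#'
#' Maps each track's raw scores to `(rank - 0.5) / M` by average rank so
#' that all tracks share an identical score distribution and percentile
#' partitions are equally sized across tissues.  Ties receive the mean of
#' their rank range.  The transform is idempotent and preserves
#' within-track rank order.
#'
#' @param tracks a single [annotation_track] or a list of tracks scoring
#'   the same SNP set.
#' @return list of tracks with `norm_score` filled (a single track input
#'   returns a single track).
#' @export
quantile_normalize <- function(tracks) {
  single <- inherits(tracks, "annotation_track")
  if (single) tracks <- list(tracks)
  ref <- tracks[[1]]$snp_id
  for (tr in tracks) {
    if (!setequal(tr$snp_id, ref) || length(tr$snp_id) != length(ref)) {
      stopf("tracks must score the same SNP set ('%s' differs)",
            tr$tissue_label)
    }
  }
  out <- lapply(tracks, function(tr) {
    m <- length(tr$raw_score)
    tr$norm_score <- (rank(tr$raw_score, ties.method = "average") - 0.5) / m
    tr
  })
  if (single) out[[1]] else out
}

#' Assign percentile bins to a normalized track
#'
#' Splits the SNPs of a track into `B = 1/resolution` bins by descending
#' normalized score; bin 1 holds the highest scores and bin sizes differ by
#' at most one SNP.  Ties at bin boundaries are broken deterministically by
#' `snp_id` so binning is reproducible regardless of input order.
#'
#' @param track an [annotation_track] with `norm_score` filled.
#' @param resolution bin width as a fraction (default 0.001, i.e. 0.1%
#'   resolution giving 1000 bins).
#' @return the track with `bin` filled.
#' @export
assign_bins <- function(track, resolution = 0.001) {
  stopifnot(inherits(track, "annotation_track"))
  if (anyNA(track$norm_score)) stopf("normalize the track before binning")
  b <- 1 / resolution
  if (abs(b - round(b)) > 1e-8) {
    stopf("resolution %g does not divide 1 into an integer number of bins",
          resolution)
  }
  b <- round(b)
  m <- length(track$snp_id)
  ord <- order(-track$norm_score, track$snp_id)
  bin <- integer(m)
  bin[ord] <- as.integer(ceiling(seq_len(m) * b / m))
  track$bin <- bin
  attr(track, "n_bins") <- b
  track
}

#' Top-fraction partition of a track
#'
#' The `ceiling(f * M)` SNPs with the highest normalized scores (ties
#' broken by `snp_id`).  Partitions are nested over `f`.
#'
#' @param track a normalized [annotation_track].
#' @param f fraction in `(0, 1]`.
#' @return a [partition].
#' @export
top_fraction_partition <- function(track, f) {
  stopifnot(inherits(track, "annotation_track"))
  if (!is.numeric(f) || length(f) != 1 || f <= 0 || f > 1) {
    stopf("fraction must lie in (0, 1]")
  }
  if (anyNA(track$norm_score)) stopf("normalize the track first")
  m <- length(track$snp_id)
  k <- ceiling(f * m)
  ord <- order(-track$norm_score, track$snp_id)
  partition(track$tissue_label, list(type = "top_fraction", value = f),
            track$snp_id[ord[seq_len(k)]])
}

#' Percentile-bin partition of a track
#'
#' @param track a binned [annotation_track].
#' @param bin bin index (1 = top of the distribution).
#' @return a [partition].
#' @export
bin_partition <- function(track, bin) {
  stopifnot(inherits(track, "annotation_track"))
  if (anyNA(track$bin)) stopf("bin the track first (assign_bins)")
  partition(track$tissue_label, list(type = "bin", value = bin),
            track$snp_id[track$bin == bin])
}

#' Read / write annotation tables
#'
#' Tab-delimited with a `snp_id` column and one raw-score column per
#' tissue; binned output adds `<tissue>__bin` columns.
#'
#' @param tracks list of [annotation_track]s.
#' @param path file path.
#' @export
write_annotations <- function(tracks, path) {
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  ref <- tracks[[1]]$snp_id
  df <- data.frame(snp_id = ref)
  for (tr in tracks) {
    idx <- match(ref, tr$snp_id)
    df[[tr$tissue_label]] <- tr$raw_score[idx]
    if (!anyNA(tr$bin)) df[[paste0(tr$tissue_label, "__bin")]] <- tr$bin[idx]
  }
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!"snp_id" %in% names(df)) stopf("annotation table missing 'snp_id'")
  score_cols <- setdiff(names(df), c("snp_id", grep("__bin$", names(df),
                                                    value = TRUE)))
  lapply(score_cols, function(cn) {
    tr <- annotation_track(cn, as.character(df$snp_id), df[[cn]])
    bc <- paste0(cn, "__bin")
    if (bc %in% names(df)) tr$bin <- as.integer(df[[bc]])
    tr
  })
}

# internal: matrix of normalized scores (SNP x tissue) aligned to snp order
annotation_matrix <- function(tracks, snp_order, what = "norm_score") {
  mat <- vapply(tracks, function(tr) {
    tr[[what]][match(snp_order, tr$snp_id)]
  }, numeric(length(snp_order)))
  colnames(mat) <- vapply(tracks, `[[`, character(1), "tissue_label")
  rownames(mat) <- snp_order
  mat
}
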