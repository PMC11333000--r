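# Orchestration: single-tissue prioritization models, the iterative
# multi-tissue refinement loop (TITR) and target-population validation.
#
# Each refinement iteration offers every candidate tissue its highest
# not-yet-consumed percentile bin; the bin is LD-block-sampled against the
# cumulative model, the merged set is scored over the whole threshold
# grid, and every (tissue, threshold) model is tested against the current
# model (nested ANOVA on iteration 1, Davidson-MacKinnon J test after).
# Among significant candidates the greatest adjusted-R^2 gain wins; only
# the winner's bin cursor advances.

#' TITR run configuration
#'
#' @param alpha per-iteration selection level for the ANOVA / J tests.
#' @param max_iterations iteration cap (default 200).
#' @param clump_r2,clump_window_kb,clump_p_ceiling clumping parameters.
#' @param ld_window_kb LD-score window.
#' @param n_thresholds,p_min,p_max threshold-grid parameters.
#' @param bin_resolution percentile bin width (default 0.001 = 1000 bins).
#' @param n_tissues Bonferroni denominator for candidate selection
#'   (default: the number of tracks supplied).
#' @param n_jackknife_blocks S-LDSC jackknife blocks.
#' @return list of class `titr_config`.
#' @export
titr_config <- function(alpha = 0.05, max_iterations = 200, clump_r2 = 0.2,
                        clump_window_kb = 250, clump_p_ceiling = 1.0,
                        ld_window_kb = 1000, n_thresholds = 370,
                        p_min = 1e-5, p_max = 1.0, bin_resolution = 0.001,
                        n_tissues = NULL, n_jackknife_blocks = 200) {
  structure(list(alpha = alpha, max_iterations = max_iterations,
                 clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
                 clump_p_ceiling = clump_p_ceiling,
                 ld_window_kb = ld_window_kb, n_thresholds = n_thresholds,
                 p_min = p_min, p_max = p_max,
                 bin_resolution = bin_resolution, n_tissues = n_tissues,
                 n_jackknife_blocks = n_jackknife_blocks),
            class = "titr_config")
}

# Fit S-LDSC once per tissue: shared LD scores over
# [base, baselines..., every tissue track], then per-tissue column subsets.
fit_tissue_sldsc <- function(stats, panel, tracks, baseline_annotations = NULL,
                             config = titr_config()) {
  tracks <- quantile_normalize(tracks)
  snp_order <- panel$snps$snp_id
  tmat <- annotation_matrix(tracks, snp_order)
  Ab <- cbind(base = rep(1, length(snp_order)))
  if (!is.null(baseline_annotations)) {
    bmat <- as.matrix(baseline_annotations)
    if (nrow(bmat) != length(snp_order)) {
      stopf("baseline annotations must align with panel SNPs")
    }
    if (is.null(colnames(bmat))) {
      colnames(bmat) <- paste0("baseline", seq_len(ncol(bmat)))
    }
    Ab <- cbind(Ab, bmat)
  }
  lds <- compute_ld_scores(panel, cbind(Ab, tmat),
                           window_kb = config$ld_window_kb)
  fits <- lapply(colnames(tmat), function(ts) {
    fit_sldsc(stats, subset_ld_scores(lds, c(colnames(Ab), ts)),
              n_blocks = config$n_jackknife_blocks, focal = ts)
  })
  names(fits) <- colnames(tmat)
  fits
}

#' Evaluate a fixed PRS model in a cohort
#'
#' Scores the SNP set at the given threshold and reports the adjusted-R^2
#' gain over the cohort's covariate-only null model.
#'
#' @param snps model SNP ids.
#' @param p_threshold p-value ceiling used for scoring.
#' @param stats [sumstats].
#' @param cohort list with `genotypes`, `phenotype`, `covariates`.
#' @param label provenance label for the profile.
#' @return list with `delta_r2`, `profile`, `null`, `full`.
#' @export
evaluate_model <- function(snps, p_threshold, stats, cohort, label = NULL) {
  profile <- compute_prs(cohort$genotypes, stats, snps, p_threshold, label)
  null <- fit_model(cohort$phenotype, cohort$covariates)
  if (attr(profile, "snp_count") == 0 ||
      var(profile$score[match(names(cohort$phenotype),
                              profile$sample_id)]) == 0) {
    return(list(delta_r2 = 0, profile = profile, null = null, full = null))
  }
  full <- fit_model(cohort$phenotype, cohort$covariates, profile)
  list(delta_r2 = delta_r2(full, null), profile = profile, null = null,
       full = full)
}

#' Single-tissue (and standard) P+T prioritization models
#'
#' Builds pruning-and-thresholding PRS models restricted to top-fraction
#' partitions of one annotation track (`tissue` and `surf_like` modes) or
#' to all GWAS SNPs (`standard` mode), optimizing the p-value threshold --
#' and, for annotation modes, the partition fraction -- by training-cohort
#' adjusted-R^2 gain over the covariate null model.
#'
#' @param stats [sumstats].
#' @param panel LD reference [geno_matrix] (training population).
#' @param cohort training cohort (list: `genotypes`, `phenotype`,
#'   `covariates`).
#' @param mode `"tissue"` (lead tissue from `fits`), `"surf_like"` (the
#'   supplied organism-wide `track`) or `"standard"` (all SNPs).
#' @param tracks normalized tissue tracks (tissue mode).
#' @param fits per-tissue `sldsc_fit` list (tissue mode); the lead tissue
#'   is the top [select_candidates()] entry.
#' @param track single track for `surf_like` mode.
#' @param clumps optional precomputed `clump_result`.
#' @param fractions partition fractions to scan (default
#'   `c(.01, .05, .10, .20, .50)`).
#' @param grid threshold grid.
#' @param n_boot bootstrap draws for the best model's delta-R^2 CI
#'   (0 disables).
#' @param config `titr_config` supplying clumping parameters and the
#'   Bonferroni denominator.
#' @return list of class `single_tissue_report`: `mode`, `tissue`,
#'   `table` (per-fraction optimum), `best` (fraction, threshold, snps,
#'   `delta_r2_train`, optional `ci`).
#' @export
run_single_tissue <- function(stats, panel, cohort, mode = c("tissue",
                                                             "standard",
                                                             "surf_like"),
                              tracks = NULL, fits = NULL, track = NULL,
                              clumps = NULL,
                              fractions = c(0.01, 0.05, 0.10, 0.20, 0.50),
                              grid = threshold_grid(), n_boot = 0,
                              config = titr_config()) {
  mode <- match.arg(mode)
  if (is.null(clumps)) {
    clumps <- clump(stats, panel, config$clump_r2, config$clump_window_kb,
                    config$clump_p_ceiling)
  }
  tissue <- NA_character_
  if (mode == "tissue") {
    stopifnot(!is.null(tracks), !is.null(fits))
    cand <- select_candidates(fits, config$n_tissues)
    if (length(cand) == 0) {
      stopf(paste("no tissue annotation is significantly enriched for",
                  "heritability; use mode = 'standard' or 'surf_like'"))
    }
    tissue <- cand[1]
    track <- tracks[[which(vapply(tracks, `[[`, character(1),
                                  "tissue_label") == tissue)]]
  } else if (mode == "surf_like") {
    stopifnot(!is.null(track))
    tissue <- track$tissue_label
  }
  if (!is.null(track) && anyNA(track$norm_score)) {
    track <- quantile_normalize(track)
  }
  h <- harmonize_sumstats(stats, cohort$genotypes)
  covariates <- cohort$covariates
  if (mode == "standard") {
    fractions <- NA_real_
  }
  rows <- lapply(fractions, function(f) {
    universe <- if (is.na(f)) stats$snp_id else
      top_fraction_partition(track, f)$snp_ids
    sel <- block_sample(clumps, universe)
    opt <- .pt_optimize(cohort$genotypes, h, sel, cohort$phenotype,
                        covariates, grid)
    list(fraction = f, opt = opt)
  })
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(fraction = r$fraction, p_threshold = r$opt$p_threshold,
               n_snps = r$opt$n_snps, delta_r2_train = r$opt$delta_r2)
  }))
  models <- lapply(rows, function(r) {
    list(fraction = r$fraction, p_threshold = r$opt$p_threshold,
         n_snps = r$opt$n_snps, snps = r$opt$snps, delta_r2 = r$opt$delta_r2)
  })
  names(models) <- as.character(fractions)
  best_i <- which.max(tab$delta_r2_train)
  best <- list(fraction = tab$fraction[best_i],
               p_threshold = tab$p_threshold[best_i],
               n_snps = tab$n_snps[best_i],
               snps = rows[[best_i]]$opt$snps,
               delta_r2_train = tab$delta_r2_train[best_i])
  if (n_boot > 0 && best$n_snps > 0) {
    profile <- compute_prs(cohort$genotypes, stats, best$snps,
                           best$p_threshold, "single_tissue")
    best$ci <- bootstrap_delta_r2(cohort$phenotype, covariates, profile,
                                  n_boot = n_boot)
  }
  structure(list(mode = mode, tissue = tissue, table = tab, best = best,
                 models = models, clumps = clumps),
            class = "single_tissue_report")
}

#' @export
print.single_tissue_report <- function(x, ...) {
  cat(sprintf("single_tissue_report (%s%s): best fraction %s, threshold %.3g, %d SNPs, delta R2 = %.4f\n",
              x$mode, if (!is.na(x$tissue)) paste0(": ", x$tissue) else "",
              format(x$best$fraction), x$best$p_threshold, x$best$n_snps,
              x$best$delta_r2_train))
  invisible(x)
}

#' Run the iterative tissue refinement loop
#'
#' Implements the multi-tissue PRS construction loop: (1) partition
#' heritability per tissue with S-LDSC and gate candidates on
#' `tau* > 0, p < 0.05/n_tissues`; (2) for each candidate tissue take its
#' next unconsumed percentile bin, LD-block-sample it against the current
#' model and score the merged set over the whole threshold grid in the
#' training cohort; (3) test every (tissue, threshold) candidate against
#' the current model (ANOVA on iteration 1, J test after) and merge the
#' significant candidate with the greatest adjusted-R^2 gain, advancing
#' only the winner's cursor; (4) stop when no candidate adds significant
#' information, the bins are exhausted, or `max_iterations` is reached.
#'
#' @param stats [sumstats].
#' @param panel LD reference [geno_matrix] (training population).
#' @param cohort training cohort (list: `genotypes`, `phenotype`,
#'   `covariates`; covariates should already include the coding PRS).
#' @param tracks list of [annotation_track]s (normalized/binned as
#'   needed).
#' @param baseline_annotations optional SNP x annotation conditioning
#'   matrix for the S-LDSC fits (row-aligned to the panel).
#' @param config a [titr_config].
#' @param clumps,fits optional precomputed clump structure and per-tissue
#'   S-LDSC fits (recomputed when `NULL`).
#' @return object of class `titr_state`: `log` (a `titr_log`),
#'   `model_snps`, `p_threshold`, `cursors`, `candidates`, `fits`,
#'   `clumps`, `status` and the inputs needed for validation.
#' @export
run_titr <- function(stats, panel, cohort, tracks,
                     baseline_annotations = NULL, config = titr_config(),
                     clumps = NULL, fits = NULL) {
  stopifnot(inherits(stats, "sumstats"))
  tracks <- quantile_normalize(tracks)
  tracks <- lapply(tracks, assign_bins, resolution = config$bin_resolution)
  names(tracks) <- vapply(tracks, `[[`, character(1), "tissue_label")
  n_bins <- attr(tracks[[1]], "n_bins")
  if (is.null(fits)) {
    fits <- fit_tissue_sldsc(stats, panel, tracks, baseline_annotations,
                             config)
  }
  n_tissues <- config$n_tissues %||% length(tracks)
  cand <- select_candidates(fits, n_tissues)
  state <- structure(list(model_snps = character(0),
                          p_threshold = NA_real_,
                          cursors = setNames(rep(1L, length(cand)),
                                             as.character(cand)),
                          candidates = as.character(cand),
                          log = titr_log_new(data.frame(), list()),
                          fits = fits, clumps = NULL, config = config,
                          stats = stats, status = "running"),
                     class = "titr_state")
  if (length(cand) == 0) {
    state$status <- "no_enriched_tissue"
    return(state)
  }
  if (is.null(clumps)) {
    clumps <- clump(stats, panel, config$clump_r2, config$clump_window_kb,
                    config$clump_p_ceiling)
  }
  state$clumps <- clumps
  grid <- threshold_grid(config$n_thresholds, config$p_min, config$p_max)
  h <- harmonize_sumstats(stats, cohort$genotypes)
  ids <- names(cohort$phenotype)
  X0 <- cohort$covariates[match(ids, cohort$covariates$sample_id),
                          setdiff(names(cohort$covariates), "sample_id"),
                          drop = FALSE]
  y <- as.numeric(cohort$phenotype)
  null_ctx <- .design_context(y, X0)
  current_ctx <- null_ctx
  D_all <- NULL   # lazily grown dosage cache, column-bound per candidate set
  get_dosages <- function(snp_ids) {
    Dg <- cohort$genotypes$dosages[match(ids,
                                         rownames(cohort$genotypes$dosages)),
                                   snp_ids, drop = FALSE]
    storage.mode(Dg) <- "double"
    Dg[is.na(Dg)] <- 0
    Dg
  }
  entries <- list()
  snp_lists <- list()
  iter <- 0L
  repeat {
    if (iter >= config$max_iterations) {
      state$status <- "max_iterations"
      break
    }
    iter <- iter + 1L
    test_kind <- if (iter == 1L) "anova" else "jtest"
    best <- NULL
    for (ts in state$candidates) {
      new <- character(0)
      while (state$cursors[ts] <= n_bins) {
        part <- tracks[[ts]]$snp_id[tracks[[ts]]$bin == state$cursors[ts]]
        new <- block_sample(clumps, part, state$model_snps)
        new <- intersect(new, h$snp_id)
        if (length(new)) break
        state$cursors[ts] <- state$cursors[ts] + 1L  # empty slice: skip bin
      }
      if (length(new) == 0) next
      cand_set <- c(state$model_snps, new)
      hs <- h[h$snp_id %in% cand_set, , drop = FALSE]
      hs <- hs[order(hs$p, hs$snp_id), , drop = FALSE]
      Dg <- get_dosages(hs$snp_id)
      tsr <- .threshold_scores(Dg, hs$beta, hs$p, grid)
      if (is.null(tsr$S)) next
      scr <- .screen_scores(tsr$S, null_ctx, current_ctx, test_kind)
      sig <- which(scr$p < config$alpha & scr$delta_r2 > 0)
      if (length(sig) == 0) next
      w <- sig[which.max(scr$delta_r2[sig])]
      count <- tsr$ucounts[w]
      thr <- grid[which(tsr$counts == count)[1]]
      if (is.null(best) || scr$delta_r2[w] > best$delta_r2) {
        best <- list(tissue = ts, bin = unname(state$cursors[ts]),
                     new = new, snps = hs$snp_id,
                     score = tsr$S[, w], count = count,
                     p_threshold = thr, delta_r2 = scr$delta_r2[w],
                     adj_r2 = scr$adj_r2[w], p = scr$p[w])
      }
    }
    if (is.null(best)) {
      state$status <- if (all(state$cursors > n_bins)) "bins_exhausted" else
        "no_significant_addition"
      iter <- iter - 1L
      break
    }
    state$model_snps <- c(state$model_snps, best$new)
    state$p_threshold <- best$p_threshold
    state$cursors[best$tissue] <- state$cursors[best$tissue] + 1L
    current_ctx <- .design_context(y, cbind(X0, .prs = best$score))
    entries[[iter]] <- data.frame(
      iteration = iter, tissue = best$tissue, bin = best$bin,
      p_threshold = best$p_threshold, n_added = length(best$new),
      n_cumulative = length(state$model_snps),
      delta_r2_train = best$delta_r2, selection_p = unname(best$p),
      delta_r2_valid = NA_real_)
    snp_lists[[iter]] <- best$new
  }
  if (state$status == "running") state$status <- "terminated"
  state$log <- titr_log_new(do.call(rbind, entries) %||% data.frame(),
                            snp_lists)
  state
}

#' @export
print.titr_state <- function(x, ...) {
  cat(sprintf("titr_state: %d iteration(s), %d model SNPs, status '%s'\n",
              nrow(x$log$entries), length(x$model_snps), x$status))
  if (length(x$candidates)) {
    cat("  candidate tissues:", paste(x$candidates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a refined model in a target-population cohort
#'
#' For each accepted iteration, the cumulative SNP set is scored in the
#' target cohort at that iteration's threshold and the adjusted-R^2 gain
#' over the target covariate-only null model is recorded
#' (`delta_r2_valid`).  The resulting per-iteration trace (accuracy and
#' tissue composition) is attached as attribute `"trace"`.
#'
#' @param state a `titr_state` from [run_titr()].
#' @param cohort target cohort (list: `genotypes`, `phenotype`,
#'   `covariates`).
#' @return the state with `log$entries$delta_r2_valid` filled.
#' @export
validate_titr <- function(state, cohort) {
  stopifnot(inherits(state, "titr_state"))
  k <- nrow(state$log$entries)
  if (k == 0) return(state)
  ids <- names(cohort$phenotype)
  X0 <- cohort$covariates[match(ids, cohort$covariates$sample_id),
                          setdiff(names(cohort$covariates), "sample_id"),
                          drop = FALSE]
  y <- as.numeric(cohort$phenotype)
  ctx <- .design_context(y, X0)
  cum <- character(0)
  dvalid <- numeric(k)
  for (i in seq_len(k)) {
    cum <- c(cum, state$log$snps[[i]])
    profile <- compute_prs(cohort$genotypes, state$stats, cum,
                           state$log$entries$p_threshold[i],
                           sprintf("titr_iter%03d", i))
    s <- profile$score[match(ids, profile$sample_id)]
    scr <- .screen_scores(matrix(s, ncol = 1), ctx, test = "anova")
    dvalid[i] <- scr$delta_r2[1]
  }
  state$log$entries$delta_r2_valid <- dvalid
  comp <- table(state$log$entries$tissue)
  attr(state, "trace") <- data.frame(
    iteration = state$log$entries$iteration,
    delta_r2_valid = dvalid,
    tissue = state$log$entries$tissue,
    n_cumulative = state$log$entries$n_cumulative)
  attr(state, "tissue_composition") <- comp / sum(comp)
  state
}

#' Plot the per-iteration validation trace
#'
#' Accuracy (adjusted-R^2 gain in the target cohort) against refinement
#' iteration, the in-silico analogue of the published per-iteration
#' accuracy traces.
#'
#' @param x a validated `titr_state`.
#' @param ... passed to [plot()].
#' @export
plot.titr_state <- function(x, ...) {
  tr <- attr(x, "trace")
  if (is.null(tr)) stopf("validate the state first (validate_titr)")
  plot(tr$iteration, tr$delta_r2_valid, type = "b", pch = 16,
       xlab = "TITR iteration", ylab = expression(Delta ~ R^2 ~ "(target)"),
       ...)
  invisible(x)
}

#' Fractional overlap between two SNP sets
#'
#' `|A intersect B| / |A|`; 0 with a warning when `A` is empty.
#'
#' @param model_a,model_b character vectors of SNP ids.
#' @return fraction in `[0, 1]`.
#' @export
snp_overlap <- function(model_a, model_b) {
  a <- unique(model_a)
  if (length(a) == 0) {
    warning("empty reference SNP set; overlap defined as 0")
    return(0)
  }
  length(intersect(a, unique(model_b))) / length(a)
}
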