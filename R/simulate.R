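# Two-population synthetic study generator.
#
# Genotypes follow a block latent-Gaussian haplotype model: within an LD
# block the latent variables form an AR(1) chain with population-specific
# correlation (training population > target population, emulating the
# stronger LD of European cohorts), thresholded at per-SNP minor-allele
# frequencies; a dosage is the sum of two independent haplotypes.  Blocks
# are mutually independent and separated by large physical gaps so that
# window-based LD computations see them as independent too.  This is an
# emulation with exact control of the LD contrast, not a population
# genetics model.

#' Simulation configuration
#'
#' Collects every knob of the synthetic two-population study in one
#' validated object.  All downstream generator functions derive their RNG
#' streams from `seed`, so a configuration fully determines the study.
#'
#' @param seed integer master seed.
#' @param n_snps,n_blocks number of SNPs and of independent LD blocks.
#' @param block_rho_train,block_rho_target latent AR(1) correlations in
#'   `[0, 1)` for the training and the target population (train > target
#'   emulates the longer-range LD of the training ancestry).
#' @param maf_range interval of per-SNP minor-allele frequencies (common
#'   variants only; the floor mirrors an MAF > 5% analysis).
#' @param n_gwas,n_train,n_valid,n_panel sample counts for the GWAS
#'   cohort, the training cohort, the target-population validation cohort
#'   and the LD reference panel.
#' @param h2 narrow-sense heritability of the simulated trait in `[0, 1]`.
#' @param n_causal number of causal SNPs.
#' @param causal_tissues labels of tissues whose annotation tracks are
#'   enriched for causal SNPs.
#' @param enrichment multiplier (>= 1) for the probability that a causal
#'   SNP lands in a causal tissue's top 1% annotation bin.
#' @param n_tissues number of annotation tracks (default 51).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param prevalence case fraction on the liability scale (binary traits).
#' @param control_case_ratio controls retained per case (default 4,
#'   i.e. a 4:1 control:case design).
#' @param causal_per_locus mean number of causal SNPs per causal LD block
#'   (allelic heterogeneity; 1 scatters causal SNPs uniformly, larger
#'   values cluster several causal variants inside shared LD blocks, the
#'   regime in which tagging SNPs aggregate signal in the training
#'   population but not in the target population).
#' @param coding_fraction fraction of SNPs flagged as coding (used for the
#'   coding-PRS covariate).
#' @param missing_rate per-call probability of a missing dosage.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_snps = 20000,
                       n_blocks = 1000,
                       block_rho_train = 0.95,
                       block_rho_target = 0.4,
                       maf_range = c(0.05, 0.5),
                       n_gwas = 10000,
                       n_train = 4000,
                       n_valid = 4000,
                       n_panel = 500,
                       h2 = 0.4,
                       n_causal = 400,
                       causal_tissues = c("tissue01", "tissue02"),
                       enrichment = 20,
                       n_tissues = 51,
                       trait_type = c("quantitative", "binary"),
                       prevalence = 0.1,
                       control_case_ratio = 4,
                       causal_per_locus = 3,
                       coding_fraction = 0.05,
                       missing_rate = 0) {
  trait_type <- match.arg(trait_type)
  stopifnot(is_count(seed, min = 0), is_count(n_snps), is_count(n_blocks),
            n_blocks <= n_snps, is_count(n_causal, min = 0),
            n_causal <= n_snps,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            h2 >= 0, h2 <= 1, enrichment >= 1,
            prevalence > 0, prevalence < 1, control_case_ratio >= 1,
            coding_fraction >= 0, coding_fraction <= 1,
            causal_per_locus >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (block_rho_train < 0 || block_rho_train >= 1 ||
      block_rho_target < 0 || block_rho_target >= 1) {
    stopf("block correlations must lie in [0, 1)")
  }
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  if (!all(causal_tissues %in% tissues)) {
    stopf("causal_tissues must be a subset of the generated tissue labels (%s...)",
          tissues[1])
  }
  structure(list(seed = as.integer(seed), n_snps = as.integer(n_snps),
                 n_blocks = as.integer(n_blocks),
                 block_rho_train = block_rho_train,
                 block_rho_target = block_rho_target,
                 maf_range = maf_range, n_gwas = as.integer(n_gwas),
                 n_train = as.integer(n_train), n_valid = as.integer(n_valid),
                 n_panel = as.integer(n_panel), h2 = h2,
                 n_causal = as.integer(n_causal),
                 causal_tissues = causal_tissues, enrichment = enrichment,
                 n_tissues = as.integer(n_tissues), tissues = tissues,
                 trait_type = trait_type, prevalence = prevalence,
                 control_case_ratio = control_case_ratio,
                 causal_per_locus = causal_per_locus,
                 coding_fraction = coding_fraction,
                 missing_rate = missing_rate),
            class = "sim_config")
}

#' Sample the causal SNP set of a configuration
#'
#' Clustered causal placement: causal loci are LD blocks, each holding
#' about `causal_per_locus` causal SNPs (allelic heterogeneity).
#'
#' @param config a [sim_config].
#' @param map SNP metadata (defaults to [sim_snp_map()]).
#' @return sorted character vector of causal SNP ids.
#' @export
sample_causal_snps <- function(config, map = sim_snp_map(config)) {
  local_seed(derive_seed(config$seed, "causal"), {
    cpl <- config$causal_per_locus
    if (cpl <= 1) return(sort(sample(map$snp_id, config$n_causal)))
    n_loci <- ceiling(config$n_causal / cpl)
    loci <- sample(unique(map$block), n_loci)
    picked <- character(0)
    for (b in loci) {
      in_block <- map$snp_id[map$block == b]
      k <- min(length(in_block), round(cpl))
      picked <- c(picked, sample(in_block, k))
    }
    extra <- config$n_causal - length(picked)
    if (extra > 0) {
      picked <- c(picked, sample(setdiff(map$snp_id, picked), extra))
    } else if (extra < 0) {
      picked <- sample(picked, config$n_causal)
    }
    sort(picked)
  })
}

#' SNP metadata of a simulated study
#'
#' Deterministic per-configuration variant table: block assignment,
#' chromosome, position, alleles and MAF.  Blocks are laid out
#' contiguously over 22 chromosomes with 2 Mb between block starts and
#' 1 kb between SNPs inside a block, so distinct blocks never share an LD
#' window; block sizes are heterogeneous around `n_snps / n_blocks`.
#'
#' @param config a [sim_config].
#' @return data.frame with `snp_id`, `chr`, `pos`, `a1`, `a2`, `maf`,
#'   `block`.
#' @export
sim_snp_map <- function(config) {
  local_seed(derive_seed(config$seed, "snp_map"), {
    m <- config$n_snps
    nb <- config$n_blocks
    # heterogeneous block sizes (mean m/nb): LD-score variation across the
    # genome is what identifies the regression slope against the intercept
    w <- runif(nb, 0.25, 1.75)
    sizes <- pmax(2, diff(round(cumsum(c(0, w)) / sum(w) * m)))
    sizes[nb] <- sizes[nb] + (m - sum(sizes))
    if (sizes[nb] < 2) {  # rebalance if the correction emptied the tail
      deficit <- 2 - sizes[nb]
      sizes[which.max(sizes)] <- sizes[which.max(sizes)] - deficit
      sizes[nb] <- 2
    }
    block <- rep(seq_len(nb), sizes)
    per_chr <- ceiling(nb / 22)
    chr_of_block <- (seq_len(nb) - 1) %/% per_chr + 1
    idx_in_chr <- stats::ave(seq_len(nb), chr_of_block, FUN = seq_along)
    within <- unlist(lapply(sizes, seq_len), use.names = FALSE)
    pos <- (idx_in_chr[block] - 1) * 2e6 + (within - 1) * 1000 + 1
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    a1 <- sample(VALID_ALLELES, m, replace = TRUE)
    # draw the other allele from the non-complementary pair so no SNP is
    # strand-ambiguous and allele harmonization never drops simulated SNPs
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    a2 <- vapply(a1, function(x) sample(setdiff(VALID_ALLELES,
                                                c(x, comp[[x]])), 1),
                 character(1))
    data.frame(snp_id = sprintf("rs%06d", seq_len(m)),
               chr = chr_of_block[block], pos = pos, a1 = a1, a2 = a2,
               maf = maf, block = block, stringsAsFactors = FALSE)
  })
}

#' Simulate genotype dosages for one population
#'
#' Haplotypes are drawn from a per-block latent AR(1) Gaussian with the
#' population's correlation parameter and thresholded at each SNP's MAF
#' quantile; a dosage is the sum of two independent haplotypes.  SNP
#' metadata (positions, alleles, MAFs, block structure) is identical across
#' populations and cohorts of the same configuration.
#'
#' @param config a [sim_config].
#' @param population `"train"` or `"target"` (chooses the LD strength).
#' @param n number of samples (>= 2).
#' @param sample_prefix prefix for generated sample ids (cohorts drawn
#'   from the same population should use distinct prefixes).
#' @param seed RNG seed; defaults to a stream derived from the config seed,
#'   the population and the prefix, so repeated calls are bitwise identical.
#' @return a [geno_matrix] whose variant table also carries the true
#'   `maf` and `block` columns.
#' @export
simulate_genotypes <- function(config, population = c("train", "target"), n,
                               sample_prefix = NULL, seed = NULL) {
  population <- match.arg(population)
  stopifnot(inherits(config, "sim_config"), is_count(n, min = 2))
  rho <- switch(population, train = config$block_rho_train,
                target = config$block_rho_target)
  if (rho >= 1) stopf("block correlation must be < 1")
  sample_prefix <- sample_prefix %||% population
  seed <- seed %||% derive_seed(config$seed,
                                paste0("geno_", population, "_", sample_prefix))
  map <- sim_snp_map(config)
  m <- nrow(map)
  thr <- qnorm(map$maf)
  dos <- matrix(0L, nrow = n, ncol = m)
  local_seed(seed, {
    chol_cache <- list()
    ar1_chol <- function(s) {
      key <- as.character(s)
      if (is.null(chol_cache[[key]])) {
        chol_cache[[key]] <<- chol(rho^abs(outer(seq_len(s), seq_len(s), "-")))
      }
      chol_cache[[key]]
    }
    for (b in unique(map$block)) {
      cols <- which(map$block == b)
      s <- length(cols)
      z <- matrix(rnorm(2L * n * s), 2L * n, s)
      if (s > 1 && rho > 0) z <- z %*% ar1_chol(s)
      hap <- sweep(z, 2, thr[cols], "<") + 0L
      dos[, cols] <- hap[seq_len(n), , drop = FALSE] +
        hap[n + seq_len(n), , drop = FALSE]
    }
    if (config$missing_rate > 0) {
      miss <- runif(length(dos)) < config$missing_rate
      dos[miss] <- NA_integer_
    }
  })
  rownames(dos) <- sprintf("%s%05d", sample_prefix, seq_len(n))
  geno_matrix(dos, map, population)
}

#' Simulate tissue annotation tracks
#'
#' Every track's non-causal scores are i.i.d. Beta(1, 4).  In tissues
#' listed in `config$causal_tissues`, causal SNPs draw their quantile
#' position from a Lehmann-tilted distribution `U^(1/kappa)` with `kappa`
#' calibrated so that the probability of a causal SNP falling in the
#' track's top 1% bin equals `min(enrichment * 0.01, 1)` (accounting for
#' the causal mass itself shifting the top-percentile cutoff).  Non-causal
#' tissues score SNPs independently of causal status.  All tracks are
#' returned quantile-normalized and binned at 0.1% resolution.
#'
#' @param config a [sim_config] (requires `enrichment >= 1`).
#' @param causal_snps character vector of causal SNP ids.
#' @param snp_ids full SNP universe; defaults to the configuration's map.
#' @param seed RNG seed (defaults to a config-derived stream).
#' @return list of [annotation_track]s, one per tissue.
#' @export
simulate_annotations <- function(config, causal_snps, snp_ids = NULL,
                                 seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$enrichment < 1) stopf("enrichment must be >= 1")
  snp_ids <- snp_ids %||% sim_snp_map(config)$snp_id
  if (!all(causal_snps %in% snp_ids)) {
    stopf("causal_snps must be a subset of the simulated SNPs")
  }
  seed <- seed %||% derive_seed(config$seed, "annotations")
  m <- length(snp_ids)
  is_causal <- snp_ids %in% causal_snps
  cfrac <- mean(is_causal)
  p_top <- min(config$enrichment * 0.01, 1)
  # solve for the tilt: the top 1% of the *mixture* must catch causal SNPs
  # with probability p_top, so the non-causal cutoff quantile q satisfies
  # (1 - cfrac) (1 - q) + cfrac (1 - q^kappa) = 0.01 with 1 - q^kappa = p_top
  tail_nc <- (0.01 - cfrac * p_top) / (1 - cfrac)
  if (cfrac > 0 && tail_nc <= 0) {
    # more boosted causal mass than top-1% slots: saturate the bin
    p_top <- 0.999 * 0.01 / cfrac
    tail_nc <- (0.01 - cfrac * p_top) / (1 - cfrac)
    titr_log("simulate_annotations: enrichment saturates the top 1%% bin; capped")
  }
  kappa <- if (p_top >= 1) Inf else log(1 - p_top) / log(1 - tail_nc)
  tracks <- local_seed(seed, {
    lapply(config$tissues, function(ts) {
      u <- runif(m)
      if (ts %in% config$causal_tissues && any(is_causal)) {
        nc <- sum(is_causal)
        u[is_causal] <- if (is.infinite(kappa)) {
          runif(nc, 1 - tail_nc, 1)
        } else {
          runif(nc)^(1 / kappa)
        }
      }
      annotation_track(ts, snp_ids, qbeta(u, 1, 4))
    })
  })
  tracks <- quantile_normalize(tracks)
  lapply(tracks, assign_bins)
}

#' Draw causal effect sizes
#'
#' Per-SNP effects on standardized genotypes are `N(0, h2 / n_causal)`
#' in magnitude distribution.  Causal SNPs sharing an LD block (an
#' allelic series at one locus) act in a concordant direction: the sign
#' is drawn once per block, so a tagging SNP in strong LD with the whole
#' series aggregates its signal.
#'
#' @param config a [sim_config].
#' @param causal_snps causal SNP ids (length used as `n_causal`).
#' @param map SNP metadata from the configuration (block membership).
#' @param seed RNG seed.
#' @return named numeric vector of per-SNP effects.
#' @export
draw_effects <- function(config, causal_snps, map = sim_snp_map(config),
                         seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, "effects")
  k <- length(causal_snps)
  if (k == 0) return(setNames(numeric(0), character(0)))
  blocks <- map$block[match(causal_snps, map$snp_id)]
  local_seed(seed, {
    sigma <- sqrt(config$h2 / max(k, 1))
    if (config$causal_per_locus > 1) {
      mag <- abs(rnorm(k, 0, sigma))
      ub <- unique(blocks)
      block_sign <- setNames(sample(c(-1, 1), length(ub), replace = TRUE),
                             ub)
      setNames(mag * block_sign[as.character(blocks)], causal_snps)
    } else {
      setNames(rnorm(k, 0, sigma), causal_snps)
    }
  })
}

#' Simulate a phenotype and covariate table for a cohort
#'
#' The quantitative phenotype is `sum(standardized dosage * beta)` plus
#' small fixed age and sex effects plus Gaussian noise scaled so that the
#' genetic variance fraction equals `config$h2`.  For binary traits, cases
#' are liabilities above the `1 - prevalence` quantile and controls are
#' subsampled to `floor(control_case_ratio) * n_cases`.  Principal
#' components are computed from the cohort's genotypes and attached to the
#' covariates; `coding_prs` is initialized to 0 and filled later by
#' [build_coding_covariate()].
#'
#' @param genotypes cohort [geno_matrix].
#' @param config a [sim_config].
#' @param effects named per-causal-SNP effect vector (see [draw_effects]).
#' @param with_pcs compute and attach 10 PCs (disable for cohorts whose
#'   covariates are never used, e.g. a marginal-GWAS cohort).
#' @param seed RNG seed.
#' @return list with `phenotype` (named vector; 0/1 for binary),
#'   `covariates` (data.frame) and `sample_ids` (samples retained after
#'   any case/control subsampling).
#' @export
simulate_phenotype <- function(genotypes, config, effects, with_pcs = TRUE,
                               seed = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  if (length(effects) && !all(names(effects) %in% genotypes$snps$snp_id)) {
    stopf("effects must be indexed by simulated SNP ids")
  }
  seed <- seed %||% derive_seed(config$seed,
                                paste0("pheno_", rownames(genotypes$dosages)[1]))
  n <- nrow(genotypes$dosages)
  g <- numeric(n)
  if (length(effects)) {
    d <- genotypes$dosages[, names(effects), drop = FALSE]
    storage.mode(d) <- "double"
    d[is.na(d)] <- 0
    mu <- colMeans(d)
    sdv <- apply(d, 2, sd)
    sdv[sdv == 0] <- 1
    z <- sweep(sweep(d, 2, mu, "-"), 2, sdv, "/")
    g <- as.vector(z %*% effects)
  }
  local_seed(seed, {
    age <- round(runif(n, 40, 70))
    sex <- rbinom(n, 1, 0.5)
    var_g <- var(g)
    # rescale the genetic component to variance h2 and the noise to
    # 1 - h2, so the genetic variance fraction is exact (h2 = 0 removes
    # the genetic term entirely)
    g <- if (config$h2 > 0 && var_g > 0) {
      g * sqrt(config$h2 / var_g)
    } else 0 * g
    y <- g + 0.05 * as.vector(scale(age)) + 0.1 * sex +
      rnorm(n, 0, sqrt(1 - config$h2))
    ids <- rownames(genotypes$dosages)
    names(y) <- ids
    covars <- data.frame(sample_id = ids, age = age, sex = sex,
                         stringsAsFactors = FALSE)
    if (with_pcs) {
      pcs <- compute_pcs(genotypes, k = 10)
      covars <- cbind(covars, pcs[match(ids, pcs$sample_id), -1, drop = FALSE])
    }
    covars$coding_prs <- 0
    if (config$trait_type == "quantitative") {
      list(phenotype = y, covariates = covars, sample_ids = ids)
    } else {
      cut <- quantile(y, 1 - config$prevalence, type = 7)
      case <- y > cut
      n_cases <- sum(case)
      n_controls <- floor(config$control_case_ratio) * n_cases
      if (sum(!case) < n_controls) {
        stopf("only %d controls available but %d required for a %g:1 design",
              sum(!case), n_controls, floor(config$control_case_ratio))
      }
      keep <- c(ids[case], sample(ids[!case], n_controls))
      keep <- keep[order(match(keep, ids))]
      pheno <- setNames(as.numeric(case[match(keep, ids)]), keep)
      list(phenotype = pheno,
           covariates = covars[match(keep, covars$sample_id), , drop = FALSE],
           sample_ids = keep)
    }
  })
}

#' Marginal GWAS on a simulated cohort
#'
#' Per-SNP simple linear regression of the phenotype on dosage: effect
#' estimate, standard error, p-value, `chi2 = (beta/se)^2` and per-SNP
#' effective sample size (non-missing calls).  Monomorphic SNPs are
#' dropped with a logged count.  Valid in both summary-statistic dialects.
#'
#' @param genotypes GWAS cohort [geno_matrix].
#' @param phenotype named numeric vector (matched to samples by name).
#' @param chunk_size SNPs processed per block (memory control).
#' @return a [sumstats] object.
#' @export
simulate_gwas <- function(genotypes, phenotype, chunk_size = 2000) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  ids <- intersect(rownames(genotypes$dosages), names(phenotype))
  if (length(ids) < 50) stopf("GWAS needs at least 50 phenotyped samples")
  y <- phenotype[ids]
  m <- ncol(genotypes$dosages)
  beta <- se <- pv <- numeric(m)
  n_eff <- integer(m)
  frq <- numeric(m)
  row_idx <- match(ids, rownames(genotypes$dosages))
  for (start in seq(1, m, by = chunk_size)) {
    cols <- start:min(start + chunk_size - 1, m)
    d <- genotypes$dosages[row_idx, cols, drop = FALSE]
    storage.mode(d) <- "double"
    if (anyNA(d)) {
      res <- vapply(seq_along(cols), function(j) {
        okj <- !is.na(d[, j])
        x <- d[okj, j]
        yy <- y[okj]
        nj <- length(x)
        sxx <- sum((x - mean(x))^2)
        if (nj < 3 || sxx == 0) return(c(NA, NA, NA, nj, mean(x) / 2))
        b <- sum((x - mean(x)) * (yy - mean(yy))) / sxx
        rss <- sum((yy - mean(yy))^2) - b^2 * sxx
        s <- sqrt(max(rss, 0) / (nj - 2) / sxx)
        tt <- b / s
        c(b, s, pchisq(tt^2, 1, lower.tail = FALSE), nj, mean(x) / 2)
      }, numeric(5))
      beta[cols] <- res[1, ]; se[cols] <- res[2, ]; pv[cols] <- res[3, ]
      n_eff[cols] <- as.integer(res[4, ]); frq[cols] <- res[5, ]
    } else {
      n <- length(y)
      mu <- colMeans(d)
      xc <- sweep(d, 2, mu, "-")
      sxx <- colSums(xc^2)
      yc <- y - mean(y)
      sxy <- as.vector(crossprod(xc, yc))
      b <- ifelse(sxx > 0, sxy / sxx, NA_real_)
      rss <- pmax(sum(yc^2) - b^2 * sxx, 0)
      s <- sqrt(rss / (n - 2) / sxx)
      tt <- b / s
      beta[cols] <- b; se[cols] <- s
      pv[cols] <- pchisq(tt^2, 1, lower.tail = FALSE)
      n_eff[cols] <- n
      frq[cols] <- mu / 2
    }
  }
  ok <- !is.na(beta) & !is.na(se) & se > 0
  if (sum(!ok)) titr_log("simulate_gwas: dropped %d monomorphic SNP(s)",
                         sum(!ok))
  snps <- genotypes$snps
  pv <- pmin(pmax(pv, 1e-320), 1)
  sumstats(data.frame(snp_id = snps$snp_id[ok], chr = snps$chr[ok],
                      pos = snps$pos[ok], a1 = snps$a1[ok], a2 = snps$a2[ok],
                      beta = beta[ok], se = se[ok], p = pv[ok],
                      chi2 = (beta[ok] / se[ok])^2, n_eff = n_eff[ok],
                      maf = pmin(frq[ok], 1 - frq[ok])))
}

#' Simulate a complete two-population PRS study
#'
#' Generates, deterministically from `config$seed`: an LD reference panel
#' and a GWAS cohort in the training population, a training cohort
#' (training population) and a validation cohort (target population),
#' causal SNPs and effects, 51 annotation tracks, phenotypes/covariates for
#' every cohort and marginal GWAS summary statistics from the GWAS cohort.
#'
#' @param config a [sim_config].
#' @param keep_gwas_genotypes retain the (large) GWAS cohort genotypes in
#'   the returned object.
#' @return list with elements `config`, `truth` (causal SNPs, effects,
#'   causal tissues, coding SNPs), `sumstats`, `panel`, `tracks`, and the
#'   `train` / `valid` cohorts (each a list of `genotypes`, `phenotype`,
#'   `covariates`).
#' @export
simulate_study <- function(config, keep_gwas_genotypes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  map <- sim_snp_map(config)
  causal <- sample_causal_snps(config, map)
  coding <- local_seed(derive_seed(config$seed, "coding"),
                       sort(sample(map$snp_id,
                                   round(config$coding_fraction * nrow(map)))))
  effects <- draw_effects(config, causal, map)
  tracks <- simulate_annotations(config, causal, map$snp_id)

  panel <- simulate_genotypes(config, "train", config$n_panel, "panel")
  gwas_geno <- simulate_genotypes(config, "train", config$n_gwas, "gwas")
  gwas_phen <- simulate_phenotype(gwas_geno, config, effects,
                                  with_pcs = FALSE,
                                  seed = derive_seed(config$seed, "pheno_gwas"))
  keep <- gwas_phen$sample_ids
  stats <- simulate_gwas(
    if (length(keep) < nrow(gwas_geno$dosages)) {
      geno_matrix(gwas_geno$dosages[keep, , drop = FALSE], gwas_geno$snps,
                  gwas_geno$population)
    } else gwas_geno,
    gwas_phen$phenotype)
  if (!keep_gwas_genotypes) {
    # the GWAS cohort is by far the largest object; release it before the
    # per-cohort simulations allocate theirs
    rm(gwas_geno)
    gc(FALSE)
  }

  make_cohort <- function(pop, n, prefix) {
    geno <- simulate_genotypes(config, pop, n, prefix)
    ph <- simulate_phenotype(geno, config, effects,
                             seed = derive_seed(config$seed,
                                                paste0("pheno_", prefix)))
    if (length(ph$sample_ids) < nrow(geno$dosages)) {
      geno <- geno_matrix(geno$dosages[ph$sample_ids, , drop = FALSE],
                          geno$snps, geno$population)
    }
    list(genotypes = geno, phenotype = ph$phenotype,
         covariates = ph$covariates)
  }
  train <- make_cohort("train", config$n_train, "train")
  valid <- make_cohort("target", config$n_valid, "valid")

  out <- list(config = config,
              truth = list(causal_snps = causal, effects = effects,
                           causal_tissues = config$causal_tissues,
                           coding_snps = coding),
              sumstats = stats, panel = panel, tracks = tracks,
              train = train, valid = valid)
  if (keep_gwas_genotypes) {
    out$gwas <- list(genotypes = gwas_geno, phenotype = gwas_phen$phenotype)
  }
  out
}

#' Write / read a simulated study as plain-text files
#'
#' Persists every component of a [simulate_study()] result under a
#' directory: dosage-text genotypes for panel/train/valid, both
#' summary-statistic dialects, the annotation table, phenotypes,
#' covariates and a truth file.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(study$panel, file.path(dir, "panel"))
  write_genotypes(study$train$genotypes, file.path(dir, "train"))
  write_genotypes(study$valid$genotypes, file.path(dir, "valid"))
  write_sumstats(study$sumstats, file.path(dir, "gwas.scoring.tsv"), "scoring")
  write_sumstats(study$sumstats, file.path(dir, "gwas.heritability.tsv"),
                 "heritability")
  write_annotations(study$tracks, file.path(dir, "annotations.tsv"))
  for (coh in c("train", "valid")) {
    ph <- data.frame(sample_id = names(study[[coh]]$phenotype),
                     phenotype = as.numeric(study[[coh]]$phenotype))
    data.table::fwrite(ph, file.path(dir, paste0(coh, ".phenotype.tsv")),
                       sep = "\t")
    write_covariates(study[[coh]]$covariates,
                     file.path(dir, paste0(coh, ".covariates.tsv")))
  }
  truth <- data.frame(snp_id = study$truth$causal_snps,
                      effect = as.numeric(study$truth$effects[
                        study$truth$causal_snps]))
  data.table::fwrite(truth, file.path(dir, "truth.causal.tsv"), sep = "\t")
  data.table::fwrite(data.frame(snp_id = study$truth$coding_snps),
                     file.path(dir, "truth.coding.tsv"), sep = "\t")
  writeLines(study$truth$causal_tissues,
             file.path(dir, "truth.causal_tissues.txt"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  read_cohort <- function(coh, pop) {
    ph <- data.table::fread(file.path(dir, paste0(coh, ".phenotype.tsv")),
                            data.table = FALSE)
    list(genotypes = read_genotypes(file.path(dir, coh), population = pop),
         phenotype = setNames(ph$phenotype, as.character(ph$sample_id)),
         covariates = read_covariates(file.path(dir,
                                                paste0(coh, ".covariates.tsv"))))
  }
  truth_causal <- data.table::fread(file.path(dir, "truth.causal.tsv"),
                                    data.table = FALSE)
  stats <- read_sumstats(file.path(dir, "gwas.scoring.tsv"), "scoring")
  her <- read_sumstats(file.path(dir, "gwas.heritability.tsv"),
                       "heritability")
  stats$n_eff <- her$n_eff[match(stats$snp_id, her$snp_id)]
  list(sumstats = stats,
       panel = read_genotypes(file.path(dir, "panel"), population = "train"),
       tracks = read_annotations(file.path(dir, "annotations.tsv")),
       train = read_cohort("train", "train"),
       valid = read_cohort("valid", "target"),
       truth = list(causal_snps = as.character(truth_causal$snp_id),
                    effects = setNames(truth_causal$effect,
                                       truth_causal$snp_id),
                    coding_snps = as.character(
                      data.table::fread(file.path(dir, "truth.coding.tsv"),
                                        data.table = FALSE)$snp_id),
                    causal_tissues = readLines(
                      file.path(dir, "truth.causal_tissues.txt"))))
}
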