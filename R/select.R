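# Regression modeling and statistical model selection: the covariate null
# model, adjusted R^2 gains, the nested-model ANOVA F test, the
# Davidson-MacKinnon J test for non-nested models, and bootstrap
# confidence intervals for delta adjusted R^2.
#
# Binary phenotypes are modeled with ordinary least squares too: the gain
# in (adjusted) R^2 on the observed 0/1 scale is the accuracy metric
# throughout, so one linear framework serves both trait types.

#' Fit a phenotype regression model
#'
#' Ordinary least squares of the phenotype on the covariate columns plus
#' any extra predictor columns (typically PRS profiles).
#'
#' @param phenotype named numeric vector.
#' @param covariates data.frame with `sample_id` plus covariate columns
#'   (intercept added automatically).
#' @param extra named list / data.frame of additional predictor columns,
#'   or a single `prs_profile` (its `score` is added as column `prs`).
#' @param allow_aliased keep (drop from the fit) rank-deficient extra
#'   columns instead of erroring; default `FALSE` errors naming the
#'   collinear columns.
#' @return object of class `titr_model`: list with the underlying `fit`
#'   (an `lm`), `r2`, `adj_r2`, `n`, `p` (non-intercept predictors),
#'   `response` and `design` (data.frame of predictors).
#' @export
fit_model <- function(phenotype, covariates, extra = NULL,
                      allow_aliased = FALSE) {
  ids <- names(phenotype)
  stopifnot(!is.null(ids), "sample_id" %in% names(covariates))
  idx <- match(ids, covariates$sample_id)
  if (anyNA(idx)) stopf("covariates missing for %d sample(s)", sum(is.na(idx)))
  d <- covariates[idx, setdiff(names(covariates), "sample_id"), drop = FALSE]
  if (!is.null(extra)) {
    if (inherits(extra, "prs_profile")) {
      extra <- data.frame(prs = extra$score[match(ids, extra$sample_id)])
    }
    extra <- as.data.frame(extra)
    if (nrow(extra) != length(ids)) stopf("extra columns have wrong length")
    d <- cbind(d, extra)
  }
  if (anyNA(d)) stopf("design contains missing values")
  dup <- duplicated(names(d))
  if (any(dup)) {
    stopf("rank-deficient design; collinear column(s): %s",
          paste(unique(names(d)[dup]), collapse = ", "))
  }
  # constant columns (e.g. a coding PRS fixed at 0) carry no information
  const <- vapply(d, function(x) var(x) == 0, logical(1))
  d <- d[, !const, drop = FALSE]
  y <- as.numeric(phenotype)
  n <- length(y)
  if (n <= ncol(d) + 1) stopf("need n > p + 1 observations")
  dat <- cbind(data.frame(.y = y), d)
  fit <- lm(.y ~ ., data = dat)
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased) && !allow_aliased) {
    stopf("rank-deficient design; collinear column(s): %s",
          paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  structure(list(fit = fit, r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 n = n, p = fit$rank - 1, response = y, design = d,
                 design_names = names(d)),
            class = "titr_model")
}

#' @export
print.titr_model <- function(x, ...) {
  cat(sprintf("titr_model: n = %d, predictors = %d, R2 = %.4f, adj R2 = %.4f\n",
              x$n, x$p, x$r2, x$adj_r2))
  invisible(x)
}

#' Gain in adjusted R^2 between two models
#'
#' @param full,null `titr_model`s fitted to the same response vector.
#' @return `full$adj_r2 - null$adj_r2` (may be negative).
#' @export
delta_r2 <- function(full, null) {
  stopifnot(inherits(full, "titr_model"), inherits(null, "titr_model"))
  if (full$n != null$n || !isTRUE(all.equal(full$response, null$response))) {
    stopf("models must share the same response vector")
  }
  full$adj_r2 - null$adj_r2
}

#' ANOVA test for nested linear models
#'
#' F test of the restriction from `full` to `null`; the null model's
#' design columns must be a subset of the full model's.  When the added
#' columns contribute no degrees of freedom (aliased, e.g. an all-zero
#' column retained with `allow_aliased = TRUE`), p = 1 by convention.
#'
#' @param null,full nested `titr_model`s.
#' @return the F-test p-value, with the F statistic and degrees of freedom
#'   attached as attributes.
#' @export
anova_nested <- function(null, full) {
  stopifnot(inherits(null, "titr_model"), inherits(full, "titr_model"))
  if (!isTRUE(all.equal(null$response, full$response))) {
    stopf("models must share the same response vector")
  }
  if (!all(null$design_names %in% full$design_names)) {
    stopf("models are not nested; use j_test for non-nested models")
  }
  rss0 <- deviance(null$fit)
  rss1 <- deviance(full$fit)
  ddf <- df.residual(null$fit) - df.residual(full$fit)
  df1 <- df.residual(full$fit)
  if (ddf <= 0) {
    p <- 1
    f <- 0
  } else {
    f <- ((rss0 - rss1) / ddf) / (rss1 / df1)
    f <- max(f, 0)
    p <- pf(f, ddf, df1, lower.tail = FALSE)
  }
  structure(p, F = f, df = c(ddf, df1))
}

#' Davidson-MacKinnon J test for non-nested linear models
#'
#' The current model's design is augmented with the challenger model's
#' fitted values; the two-sided t-test p-value of that extra coefficient
#' is returned.  A small p-value means the challenger carries information
#' the current model lacks.  When the challenger's fitted values are
#' collinear with the current design (e.g. identical models), p = 1 with
#' a warning.
#'
#' @param current,challenger `titr_model`s on the same response.
#' @return the p-value, with the t statistic attached as an attribute.
#' @export
j_test <- function(current, challenger) {
  stopifnot(inherits(current, "titr_model"), inherits(challenger, "titr_model"))
  if (!isTRUE(all.equal(current$response, challenger$response))) {
    stopf("models must share the same response vector")
  }
  d <- current$design
  d$.challenger_fit <- fitted(challenger$fit)
  dat <- cbind(data.frame(.y = current$response), d)
  fit <- lm(.y ~ ., data = dat)
  cf <- coef(fit)[".challenger_fit"]
  if (is.na(cf)) {
    warning("challenger fitted values are collinear with the current design; p = 1")
    return(structure(1, t = 0))
  }
  sm <- summary(fit)$coefficients
  structure(unname(sm[".challenger_fit", "Pr(>|t|)"]),
            t = unname(sm[".challenger_fit", "t value"]))
}

#' Bootstrap confidence interval for delta adjusted R^2
#'
#' Samples are resampled with replacement `n_boot` times; the null
#' (covariates) and full (covariates + PRS) models are refitted on each
#' resample and the percentile 95% CI of the adjusted-R^2 gain is
#' returned.  Degenerate resamples with a constant phenotype are redrawn
#' (logged).
#'
#' @param phenotype named numeric vector (n >= 30).
#' @param covariates covariate data.frame.
#' @param prs a `prs_profile` (or named numeric vector of scores).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed; fixed seeds reproduce the CI bitwise.
#' @return numeric `c(lower, upper)` (2.5% / 97.5% percentiles) with the
#'   point estimate and bootstrap draws attached as attributes.
#' @export
bootstrap_delta_r2 <- function(phenotype, covariates, prs, n_boot = 1000,
                               seed = 1) {
  ids <- names(phenotype)
  if (length(ids) < 30) stopf("bootstrap needs at least 30 samples")
  X0 <- as.matrix(cbind(
    1, covariates[match(ids, covariates$sample_id),
                  setdiff(names(covariates), "sample_id"), drop = FALSE]))
  s <- if (inherits(prs, "prs_profile")) {
    prs$score[match(ids, prs$sample_id)]
  } else as.numeric(prs[ids])
  y <- as.numeric(phenotype)
  n <- length(y)
  X1 <- cbind(X0, s)
  adj <- function(X, yy) {
    f <- .lm.fit(X, yy)
    rss <- sum(f$residuals^2)
    tss <- sum((yy - mean(yy))^2)
    .adj_r2_from_rss(rss, tss, length(yy), ncol(X))
  }
  point <- adj(X1, y) - adj(X0, y)
  redrawn <- 0L
  draws <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (var(y[idx]) > 0) break
        redrawn <<- redrawn + 1L
        if (redrawn > 100L) stopf("phenotype degenerate under resampling")
      }
      adj(X1[idx, , drop = FALSE], y[idx]) - adj(X0[idx, , drop = FALSE],
                                                 y[idx])
    }, numeric(1))
  })
  if (redrawn) titr_log("bootstrap_delta_r2: redrew %d degenerate resample(s)",
                        redrawn)
  ci <- unname(quantile(draws, c(0.025, 0.975), type = 7))
  structure(ci, point = point, draws = draws)
}
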