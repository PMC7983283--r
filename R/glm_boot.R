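#' Fit the logistic multiple regression by maximum likelihood
#'
#' Models the per-cell condition as Bernoulli with
#' `logit(pi_i) = beta_0 + x_i' beta`, where `x_i` holds all marker
#' expressions of cell i, and estimates the coefficients by IRLS. A marker
#' coefficient is its conditional log-odds association with the condition,
#' given all other markers.
#'
#' Under (quasi-)separation the MLE does not exist; the fit then falls back
#' to a weak L2 penalty (`1 / (10 * n_cells)` on the marker coefficients)
#' and flags it via `ridged`.
#'
#' @param dataset a [cytometry_dataset()] with both conditions present.
#' @param standardize center and scale each marker to unit variance before
#'   fitting (default `TRUE`) so coefficients are comparable across
#'   markers.
#' @return list with `coef` (named, intercept first), `converged`,
#'   `ridged`, `deviance`.
#' @export
fit_logistic <- function(dataset, standardize = TRUE) {
  check_fit_ready(dataset)
  if (standardize) dataset <- standardize_markers(dataset)
  x <- cbind(`(Intercept)` = 1, dataset$expressions)
  fit <- irls_logistic_cpp(x, as.numeric(dataset$condition),
                           ridge_fallback = 1 / (10 * nrow(x)))
  list(coef = setNames(as.vector(fit$coef), colnames(x)),
       converged = fit$converged, ridged = fit$ridged,
       deviance = fit$deviance)
}

#' Two-level cluster bootstrap of the logistic fit
#'
#' Nonparametric bootstrap preserving the grouping of cells within donors:
#' each replicate draws J donors with replacement, then resamples each
#' drawn donor's cells with replacement (keeping its original cell count),
#' and refits the logistic regression. Replicates whose resample carries
#' only one condition are redrawn.
#'
#' @inheritParams fit_logistic
#' @param B number of bootstrap replicates.
#' @param seed optional integer seed for the resampling.
#' @return `B x P` matrix of marker coefficients (one row per replicate;
#'   the intercept is dropped). Attribute `ridged` flags replicates fitted
#'   with the separation fallback penalty.
#' @export
cluster_bootstrap <- function(dataset, B = 1000, seed = NULL,
                              standardize = TRUE) {
  check_fit_ready(dataset)
  if (B < 1) stop("B must be at least 1")
  if (nlevels(droplevels(dataset$donor)) < 2L)
    stop("at least two donors required for the cluster bootstrap")
  if (!is.null(seed)) set.seed(seed)
  if (standardize) dataset <- standardize_markers(dataset)
  x <- cbind(1, dataset$expressions)
  donor <- as.integer(droplevels(dataset$donor)) - 1L
  res <- cluster_bootstrap_cpp(x, as.numeric(dataset$condition), donor,
                               n_donor = max(donor) + 1L, B = B,
                               ridge_fallback = 1 / (10 * nrow(x)))
  betas <- res$betas[, -1L, drop = FALSE]
  colnames(betas) <- colnames(dataset$expressions)
  attr(betas, "ridged") <- as.logical(res$ridged)
  betas
}

#' Percentile confidence intervals from bootstrap replicates
#'
#' Per-column empirical quantiles at `alpha/2` and `1 - alpha/2`
#' (type-7 interpolation, the R default, documented here because B is
#' finite).
#'
#' @param boot `B x P` matrix of bootstrap replicates.
#' @param level confidence level in (0, 1); default 0.95.
#' @return list with numeric vectors `ci_low` and `ci_high` (length P)
#' @export
percentile_ci <- function(boot, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1")
  boot <- as.matrix(boot)
  alpha <- 1 - level
  list(ci_low = apply(boot, 2, quantile, probs = alpha / 2, type = 7,
                      names = FALSE),
       ci_high = apply(boot, 2, quantile, probs = 1 - alpha / 2, type = 7,
                       names = FALSE))
}

#' p-value by inverting equal-tailed percentile intervals
#'
#' The smallest two-sided equal-tail level at which the percentile
#' interval excludes zero, with add-one smoothing so p is always positive:
#' `p = min(1, 2 * min((1 + #\{b <= 0\}) / (B + 1),
#' (1 + #\{b >= 0\}) / (B + 1)))`. Replicates exactly at zero count toward
#' both tails.
#'
#' @param boot_column numeric vector of B bootstrap replicates for one
#'   coefficient.
#' @return p-value in (0, 1]
#' @export
pvalue_from_bootstrap <- function(boot_column) {
  b <- length(boot_column)
  n_le <- sum(boot_column <= 0)
  n_ge <- sum(boot_column >= 0)
  min(1, 2 * min(1 + n_le, 1 + n_ge) / (b + 1))
}

#' Bootstrapped logistic GLM differential expression analysis
#'
#' The full pipeline for one two-group comparison: maximum-likelihood
#' logistic fit of condition on all markers jointly, two-level cluster
#' bootstrap ([cluster_bootstrap()]), percentile confidence intervals,
#' p-values by interval inversion, and BH/BY FDR adjustment across the P
#' marker hypotheses (the intercept is not tested).
#'
#' @inheritParams cluster_bootstrap
#' @param level confidence level for the percentile intervals.
#' @return an object of class `cytoglm_fit`: list with `beta_hat` (full
#'   coefficient vector, intercept first), `boot_betas` (B x P),
#'   `ci_low`, `ci_high`, `p_raw`, `p_adj_bh`, `p_adj_by` (named length-P
#'   vectors), `B`, `level`, `seed`, and the point fit's `converged` /
#'   `ridged` flags. Use [marker_table()] for a tidy per-marker summary.
#' @export
cytoglm <- function(dataset, B = 1000, level = 0.95, seed = NULL,
                    standardize = TRUE) {
  fit <- fit_logistic(dataset, standardize = standardize)
  boot <- cluster_bootstrap(dataset, B = B, seed = seed,
                            standardize = standardize)
  ci <- percentile_ci(boot, level = level)
  p_raw <- apply(boot, 2, pvalue_from_bootstrap)
  markers <- colnames(dataset$expressions)
  structure(
    list(beta_hat = fit$coef, boot_betas = boot,
         ci_low = setNames(ci$ci_low, markers),
         ci_high = setNames(ci$ci_high, markers),
         p_raw = p_raw,
         p_adj_bh = adjust_pvalues(p_raw, "bh")$p_adj,
         p_adj_by = adjust_pvalues(p_raw, "by")$p_adj,
         B = B, level = level, seed = seed,
         converged = fit$converged, ridged = fit$ridged,
         condition_levels = attr(dataset, "condition_levels")),
    class = "cytoglm_fit")
}

#' @export
print.cytoglm_fit <- function(x, ...) {
  cat("<cytoglm_fit> bootstrapped logistic GLM, B =", x$B, "replicates\n")
  lev <- x$condition_levels
  if (length(lev) == 2L)
    cat("  positive coefficients predict", lev[2L], "over", lev[1L], "\n")
  print(marker_table(x), digits = 3)
  invisible(x)
}

#' Tidy per-marker summary of a fit
#'
#' @param fit a `cytoglm_fit` or `cytoglmm_fit` object.
#' @return data.frame with one row per marker: `marker`, `coef`, `ci_low`,
#'   `ci_high`, `p`, `p_bh`, `p_by`.
#' @export
marker_table <- function(fit) UseMethod("marker_table")

#' @export
marker_table.cytoglm_fit <- function(fit) {
  markers <- names(fit$p_raw)
  data.frame(marker = markers,
             coef = unname(fit$beta_hat[markers]),
             ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
             p = unname(fit$p_raw), p_bh = unname(fit$p_adj_bh),
             p_by = unname(fit$p_adj_by), row.names = NULL)
}
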