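#' Per-donor logistic fits
#'
#' First stage of the method-of-moments GLMM: each donor's cells are fit
#' separately by logistic regression of condition on all markers
#' (intercept + P slopes), yielding a coefficient vector `theta_j` and the
#' observed Fisher information `F_j` at the estimate. Markers are
#' standardized on the full dataset (one shared scaling) so per-donor
#' coefficients are comparable.
#'
#' Donors observed under a single condition carry no within-donor contrast
#' and are excluded with a warning; if no donor has both conditions the
#' design is unpaired and the GLMM cannot estimate its donor-level random
#' effect — use [cytoglm()] instead.
#'
#' @inheritParams fit_logistic
#' @return list of per-donor fits, each with `donor`, `theta` (length
#'   P + 1), `fisher` ((P+1) x (P+1)), `converged`, `ridged`, `n_cells`.
#' @export
fit_per_donor <- function(dataset, standardize = TRUE) {
  stopifnot(inherits(dataset, "cytometry_dataset"))
  if (standardize) dataset <- standardize_markers(dataset)
  p <- n_markers(dataset)
  idx <- split(seq_along(dataset$condition), dataset$donor)
  both <- vapply(idx, function(i)
    length(unique(dataset$condition[i])) == 2L, logical(1))
  if (!any(both))
    stop("no donor has cells under both conditions: the donor-level ",
         "random effect cannot be estimated from an unpaired design; ",
         "use cytoglm() instead")
  if (any(!both))
    warning("excluding donor(s) with a single condition: ",
            paste(names(idx)[!both], collapse = ", "))
  enough <- vapply(idx, length, integer(1)) >= p + 2L
  if (any(both & !enough))
    warning("excluding donor(s) with fewer than P + 2 cells: ",
            paste(names(idx)[both & !enough], collapse = ", "))
  keep <- names(idx)[both & enough]
  lapply(keep, function(d) {
    i <- idx[[d]]
    x <- cbind(`(Intercept)` = 1, dataset$expressions[i, , drop = FALSE])
    fit <- irls_logistic_cpp(x, as.numeric(dataset$condition[i]),
                             ridge_fallback = 1 / (10 * length(i)))
    theta <- as.vector(fit$coef)
    list(donor = d, theta = setNames(theta, colnames(x)),
         fisher = fisher_info_cpp(x, theta), converged = fit$converged,
         ridged = fit$ridged, n_cells = length(i))
  })
}

# Symmetric inverse with graceful degradation: plain solve, then a
# vanishing ridge, then an eigenvalue pseudo-inverse.
safe_inv <- function(a) {
  out <- tryCatch(solve(a), error = function(e) NULL)
  if (is.null(out))
    out <- tryCatch(solve(a + diag(1e-8 * max(diag(a), 1e-12), nrow(a))),
                    error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen((a + t(a)) / 2, symmetric = TRUE)
    tol <- max(abs(e$values)) * 1e-12 + 1e-300
    out <- e$vectors %*% (ifelse(abs(e$values) > tol,
                                 1 / e$values, 0) * t(e$vectors))
  }
  (out + t(out)) / 2
}

# Clip negative eigenvalues to zero; returns the projected matrix with the
# clipped mass (sum of |negative eigenvalues|) as an attribute.
psd_project <- function(a) {
  e <- eigen((a + t(a)) / 2, symmetric = TRUE)
  clipped <- sum(abs(pmin(e$values, 0)))
  out <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  dimnames(out) <- dimnames(a)
  attr(out, "clipped_mass") <- clipped
  out
}

#' Method-of-moments combination of per-donor fits
#'
#' Second stage of the GLMM: the random-effect covariance is estimated by
#' moments as the between-donor dispersion of the per-donor coefficients
#' in excess of their within-donor sampling covariance,
#' `Sigma_hat = PSD[ cov(theta_j) - mean(F_j^-1) ]`
#' (negative eigenvalues clipped to zero), and the fixed effects are the
#' precision-weighted combination
#' `beta_hat = (sum W_j)^-1 sum W_j theta_j` with
#' `W_j = (Sigma_hat + F_j^-1)^-1`. Standard errors come from the combined
#' precision `(sum W_j)^-1` and marker p-values are two-sided Wald tests.
#' Because the fixed effects are a combination of J donor-level estimates,
#' the effective sample size for their sampling distribution is the number
#' of donors, not the number of cells; the Wald statistics are therefore
#' referred to a Student-t distribution with J - 1 degrees of freedom
#' (the normal reference is anti-conservative for the handful of donors
#' typical of immunology studies).
#'
#' @param fits output of [fit_per_donor()] (at least two donors).
#' @param sigma_structure `"unstructured"` (default) estimates the full
#'   random-effect covariance; `"diagonal"` keeps only its diagonal.
#' @return list with `beta_hat` (length P + 1), `sigma_hat`
#'   ((P+1) x (P+1), PSD), `se` and `p_raw` (named length-P, markers
#'   only), `vcov`, `theta` (J x (P+1)), `f_inv` (list), `weights` (list
#'   of W_j), `clipped_mass`.
#' @export
moment_estimate <- function(fits,
                            sigma_structure = c("unstructured",
                                                "diagonal")) {
  sigma_structure <- match.arg(sigma_structure)
  if (length(fits) < 2L)
    stop("at least two usable donors are required")
  theta <- do.call(rbind, lapply(fits, `[[`, "theta"))
  d <- ncol(theta)
  f_inv <- lapply(fits, function(f) safe_inv(f$fisher))

  # precision-weighted mean with within-donor precisions only
  f_sum <- Reduce(`+`, lapply(fits, `[[`, "fisher"))
  beta0 <- as.vector(safe_inv(f_sum) %*%
                       Reduce(`+`, lapply(fits, function(f)
                         f$fisher %*% f$theta)))
  centered <- sweep(theta, 2, beta0)
  between <- crossprod(centered) / (nrow(theta) - 1L)
  sigma_raw <- between - Reduce(`+`, f_inv) / length(f_inv)
  if (sigma_structure == "diagonal")
    sigma_raw <- diag(diag(sigma_raw), d)
  sigma_hat <- psd_project(sigma_raw)
  dimnames(sigma_hat) <- list(colnames(theta), colnames(theta))

  weights <- lapply(f_inv, function(fi) {
    w <- tryCatch(solve(sigma_hat + fi), error = function(e) NULL)
    if (is.null(w)) w <- safe_inv(fi)  # fall back to F_j-only precision
    (w + t(w)) / 2
  })
  w_sum <- Reduce(`+`, weights)
  vcov <- safe_inv(w_sum)
  theta_rows <- lapply(seq_len(nrow(theta)), function(j) theta[j, ])
  beta_hat <- as.vector(vcov %*%
                          Reduce(`+`, Map(function(w, th) w %*% th,
                                          weights, theta_rows)))
  names(beta_hat) <- colnames(theta)
  se_all <- sqrt(pmax(diag(vcov), 0))
  se <- setNames(se_all[-1L], colnames(theta)[-1L])
  df <- length(fits) - 1L
  z <- abs(beta_hat[-1L]) / se
  p_raw <- 2 * pt(-z, df = df)
  list(beta_hat = beta_hat, sigma_hat = sigma_hat, se = se,
       p_raw = p_raw, df = df, vcov = vcov, theta = theta, f_inv = f_inv,
       weights = weights,
       clipped_mass = attr(sigma_hat, "clipped_mass"))
}

#' Empirical-Bayes prediction of donor-level effects
#'
#' Shrinks each donor's deviation from the fixed effects toward zero in
#' proportion to how noisy its own fit is:
#' `u_j = Sigma_hat (Sigma_hat + F_j^-1)^-1 (theta_j - beta_hat)`.
#' With `Sigma_hat = 0` all donors collapse onto the fixed effects; with
#' infinitely precise per-donor fits `u_j -> theta_j - beta_hat`.
#'
#' @param mom output of [moment_estimate()].
#' @return J x (P+1) matrix of predicted donor effects
#' @export
predict_random_effects <- function(mom) {
  theta_rows <- lapply(seq_len(nrow(mom$theta)),
                       function(j) mom$theta[j, ])
  u <- t(mapply(function(fi, th) {
    w <- safe_inv(mom$sigma_hat + fi)
    as.vector(mom$sigma_hat %*% w %*% (th - mom$beta_hat))
  }, mom$f_inv, theta_rows))
  colnames(u) <- names(mom$beta_hat)
  u
}

#' Logistic GLMM differential expression analysis (paired designs)
#'
#' Random-coefficient logistic regression
#' `logit(pi_ij) = x_ij' (beta + u_j)` with donor effects
#' `u_j ~ N(0, Sigma)`, fitted by the two-stage moment procedure: per-donor
#' logistic fits ([fit_per_donor()]), moment estimation of `Sigma` and
#' precision-weighted fixed effects ([moment_estimate()]), empirical-Bayes
#' donor-effect prediction, and BH/BY adjustment of the marker-wise Wald
#' p-values.
#'
#' Requires a paired design: each donor must contribute cells under both
#' conditions, otherwise the donor-level random effect is not estimable.
#'
#' @inheritParams fit_logistic
#' @inheritParams moment_estimate
#' @param level confidence level for the reported Wald intervals.
#' @return an object of class `cytoglmm_fit`: list with `beta_hat`
#'   (length P + 1), `sigma_hat`, `u_hat` (J x (P+1)), `se`, `p_raw`,
#'   `p_adj_bh`, `p_adj_by`, `ci_low`, `ci_high`, `donors`,
#'   `clipped_mass`. Use [marker_table()] for a tidy per-marker summary.
#' @export
cytoglmm <- function(dataset, standardize = TRUE,
                     sigma_structure = c("unstructured", "diagonal"),
                     level = 0.95) {
  fits <- fit_per_donor(dataset, standardize = standardize)
  mom <- moment_estimate(fits, sigma_structure = sigma_structure)
  u_hat <- predict_random_effects(mom)
  rownames(u_hat) <- vapply(fits, `[[`, character(1), "donor")
  zq <- -qt((1 - level) / 2, df = mom$df)
  beta_m <- mom$beta_hat[-1L]
  structure(
    list(beta_hat = mom$beta_hat, sigma_hat = mom$sigma_hat,
         u_hat = u_hat, se = mom$se, p_raw = mom$p_raw,
         p_adj_bh = adjust_pvalues(mom$p_raw, "bh")$p_adj,
         p_adj_by = adjust_pvalues(mom$p_raw, "by")$p_adj,
         ci_low = beta_m - zq * mom$se, ci_high = beta_m + zq * mom$se,
         level = level, df = mom$df, donors = rownames(u_hat),
         clipped_mass = mom$clipped_mass,
         condition_levels = attr(dataset, "condition_levels")),
    class = "cytoglmm_fit")
}

#' @export
print.cytoglmm_fit <- function(x, ...) {
  cat("<cytoglmm_fit> moment-based logistic GLMM,",
      length(x$donors), "donors\n")
  lev <- x$condition_levels
  if (length(lev) == 2L)
    cat("  positive coefficients predict", lev[2L], "over", lev[1L], "\n")
  print(marker_table(x), digits = 3)
  invisible(x)
}

#' @export
marker_table.cytoglmm_fit <- function(fit) {
  markers <- names(fit$p_raw)
  data.frame(marker = markers,
             coef = unname(fit$beta_hat[markers]),
             ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
             p = unname(fit$p_raw), p_bh = unname(fit$p_adj_bh),
             p_by = unname(fit$p_adj_by), row.names = NULL)
}
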