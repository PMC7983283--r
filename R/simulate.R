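#' AR(1) covariance matrix
#'
#' Builds the autoregressive covariance used at both levels of the
#' hierarchical simulator: correlation `Omega[r, s] = rho^|r - s|`, scaled
#' to `Sigma = diag(sigma) %*% Omega %*% diag(sigma)`, so entry (r, s) is
#' `sigma[r] * sigma[s] * rho^|r - s|`.
#'
#' @param sigma nonnegative standard deviations, length P (a scalar is
#'   recycled).
#' @param rho AR(1) correlation, strictly inside (-1, 1).
#' @param p optional dimension when `sigma` is a scalar.
#' @return symmetric positive semidefinite P x P matrix
#' @export
ar1_covariance <- function(sigma, rho, p = length(sigma)) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1)
    stop("rho must be a single value with |rho| < 1")
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  sigma <- rep_len(sigma, p)
  omega <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  diag(sigma, p) %*% omega %*% diag(sigma, p)
}

# Symmetric PSD square root via eigendecomposition; tolerates exactly
# singular covariances (e.g. sigma = 0), unlike chol().
cov_root <- function(sigma_mat) {
  e <- eigen(sigma_mat, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulation parameters for the hierarchical Poisson generator
#'
#' Defines the data-generating mechanism: per-cell log-intensities are
#' `B_ij + U_j` with cell-level `B_ij ~ N(delta^(y), Sigma_B)` (mean
#' depending on the cell's condition y) and donor-level
#' `U_j ~ N(0, Sigma_U)` shared by all cells of donor j; counts are
#' `Poisson(exp(B_ij + U_j))`. Both covariances are AR(1)
#' ([ar1_covariance()]). Markers in the active set have
#' `delta^(1) - delta^(0) = effect > 0`; all others have a zero effect.
#'
#' @param p number of markers.
#' @param active indices of the differential (active-set) markers.
#' @param effect log-scale mean shift for active markers (stimulated minus
#'   unstimulated).
#' @param delta0 baseline log-scale mean, scalar or length-p vector.
#' @param sigma_b,sigma_u cell- and donor-level marker standard deviations
#'   (shared across markers).
#' @param rho_b,rho_u cell- and donor-level AR(1) correlations in (-1, 1).
#' @param n_donors number of donors J. In an unpaired design J must be even
#'   (J/2 donors per condition).
#' @param n_cells_per_sample cells per sample (a paired donor contributes
#'   two samples).
#' @param paired logical; paired donors contribute one sample under each
#'   condition, with the donor effect `U_j` shared across both.
#' @param lambda_cap guard against numeric overflow: simulation aborts if
#'   any Poisson intensity exceeds this cap.
#' @return an object of class `sim_params`
#' @export
sim_params <- function(p = 10, active = 1:3, effect = 1.8,
                       delta0 = log(50), sigma_b = 1, sigma_u = 1,
                       rho_b = 0, rho_u = 0, n_donors = 8,
                       n_cells_per_sample = 1000, paired = TRUE,
                       lambda_cap = 1e12) {
  if (abs(rho_b) >= 1 || abs(rho_u) >= 1)
    stop("correlations must satisfy |rho| < 1")
  if (sigma_b < 0 || sigma_u < 0) stop("sigma must be nonnegative")
  if (length(active) && (any(active < 1) || any(active > p)))
    stop("active indices must lie in 1..p")
  if (effect < 0) stop("effect must be nonnegative")
  delta0 <- rep_len(delta0, p)
  delta1 <- delta0 + effect * (seq_len(p) %in% active)
  structure(
    list(p = p, active = sort(unique(active)), effect = effect,
         delta0 = delta0, delta1 = delta1, sigma_b = sigma_b,
         sigma_u = sigma_u, rho_b = rho_b, rho_u = rho_u,
         n_donors = n_donors, n_cells_per_sample = n_cells_per_sample,
         paired = paired, lambda_cap = lambda_cap),
    class = "sim_params")
}

#' Default simulation settings
#'
#' The reference study conditions used throughout the package's power and
#' FDR experiments: 16 samples of 1000 cells with 3 of 10 markers active.
#' Paired: 8 donors, two samples each, effect 1.8 on the log scale.
#' Unpaired: 16 donors, one sample each, effect 15 (much larger effects
#' are needed for any power without a within-donor contrast); the baseline
#' is 0 there so active-marker intensities stay within floating range.
#'
#' @param design `"paired"` or `"unpaired"`.
#' @param ... overrides passed on to [sim_params()].
#' @return a [sim_params()] object
#' @export
default_sim_params <- function(design = c("paired", "unpaired"), ...) {
  design <- match.arg(design)
  defaults <- if (design == "paired") {
    list(n_donors = 8, effect = 1.8, delta0 = log(50), paired = TRUE)
  } else {
    list(n_donors = 16, effect = 15, delta0 = 0, paired = FALSE)
  }
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# Poisson draws that stay finite for huge intensities: above the threshold
# the count distribution is approximated by round(N(lambda, lambda)).
rpois_safe <- function(lambda, normal_above = 1e7) {
  x <- numeric(length(lambda))
  big <- lambda > normal_above
  if (any(!big)) x[!big] <- rpois(sum(!big), lambda[!big])
  if (any(big))
    x[big] <- pmax(0, round(rnorm(sum(big), lambda[big],
                                  sqrt(lambda[big]))))
  x
}

#' Simulate a cytometry dataset with known ground truth
#'
#' Draws from the hierarchical Poisson log-normal model described in
#' [sim_params()]. The donor effects `U_j` are drawn before any cell-level
#' quantity, so for a fixed seed they do not depend on the number of cells
#' per sample.
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer seed; the draw is bit-reproducible given
#'   the seed.
#' @return a list with `dataset` (a [cytometry_dataset()] of raw counts;
#'   apply [transform_expressions()] before fitting) and `truth` (list with
#'   `active`, a logical vector marking the differential markers, the
#'   generating `params`, and `donor_effects`, the J x P matrix of drawn
#'   donor-level log-scale shifts U_j).
#' @export
simulate_dataset <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  J <- params$n_donors
  P <- params$p
  n <- params$n_cells_per_sample
  if (!params$paired && J %% 2L != 0L)
    stop("unpaired design requires an even number of donors ",
         "(J/2 per condition)")

  sig_u <- ar1_covariance(rep(params$sigma_u, P), params$rho_u)
  sig_b <- ar1_covariance(rep(params$sigma_b, P), params$rho_b)
  u <- matrix(rnorm(J * P), J, P) %*% cov_root(sig_u)

  if (params$paired) {
    donor_idx <- rep(seq_len(J), each = 2L * n)
    cond <- rep(rep(c(0L, 1L), each = n), times = J)
  } else {
    donor_idx <- rep(seq_len(J), each = n)
    cond <- ifelse(donor_idx <= J %/% 2L, 0L, 1L)
  }
  n_total <- length(donor_idx)

  b <- matrix(rnorm(n_total * P), n_total, P) %*% cov_root(sig_b)
  delta <- rbind(params$delta0, params$delta1)
  b <- b + delta[cond + 1L, , drop = FALSE]
  log_lambda <- b + u[donor_idx, , drop = FALSE]
  lambda <- exp(log_lambda)
  if (any(lambda > params$lambda_cap))
    stop("Poisson intensity exceeded lambda_cap = ", params$lambda_cap,
         "; max log-intensity ", signif(max(log_lambda), 4),
         " (check delta/sigma settings)")
  counts <- matrix(rpois_safe(as.vector(lambda)), n_total, P)
  colnames(counts) <- paste0("M", seq_len(P))

  dataset <- cytometry_dataset(
    counts, donor = paste0("D", donor_idx), condition = cond)
  truth <- structure(
    list(active = seq_len(P) %in% params$active, params = params,
         donor_effects = u),
    class = "ground_truth")
  list(dataset = dataset, truth = truth)
}
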