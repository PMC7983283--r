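test_that("per-donor fitting enforces the paired-design contract", {
  # fully unpaired: every donor observed under one condition only
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("M1", "M2")))
  unpaired <- cytometry_dataset(x, donor = rep(1:4, each = 25),
                                condition = rep(c(0, 1), each = 50))
  expect_error(fit_per_donor(unpaired), "cytoglm")

  # mixed: one donor lacks a condition and is dropped with a warning
  ds <- make_mixed_logistic_dataset(60, 4, c(0, 0.5, -0.5), 0.1,
                                    seed = 21)
  ds$condition[ds$donor == "4"] <- 0L
  expect_warning(fits <- fit_per_donor(ds), "single condition")
  expect_length(fits, 3L)
  expect_true(all(vapply(fits, function(f)
    isSymmetric(f$fisher, tol = 1e-8), logical(1))))
})

test_that("identical donors collapse to zero between-donor covariance", {
  set.seed(22)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("M1", "M2")))
  y <- rbinom(40, 1, plogis(x[, 1]))
  # two donors carrying byte-identical cells
  ds <- cytometry_dataset(rbind(x, x), donor = rep(1:2, each = 40),
                          condition = c(y, y))
  fits <- fit_per_donor(ds, standardize = FALSE)
  expect_equal(fits[[1]]$theta, fits[[2]]$theta, tolerance = 1e-10)
  mom <- moment_estimate(fits)
  expect_equal(unname(mom$beta_hat), unname(fits[[1]]$theta),
               tolerance = 1e-6)
  expect_equal(max(abs(mom$sigma_hat)), 0, tolerance = 1e-8)
})

test_that("with no donor heterogeneity the GLMM matches the pooled GLM", {
  # all donors share one coefficient vector; between-donor dispersion is
  # at the sampling-noise level, so Sigma_hat clips to ~0 and the
  # precision-weighted combination reduces to the pooled fit
  ds <- make_mixed_logistic_dataset(4000, 6, c(0.1, 0.8, -0.5), 0,
                                    seed = 23)
  glmm <- cytoglmm(ds, standardize = FALSE)
  pooled <- fit_logistic(ds, standardize = FALSE)
  pooled_se <- sqrt(diag(solve(
    cytoreg:::fisher_info_cpp(cbind(1, ds$expressions), pooled$coef))))
  expect_lt(max(abs(glmm$beta_hat - pooled$coef) / pooled_se), 2)
  expect_lt(max(diag(glmm$sigma_hat)), 0.01)
})

test_that("moment estimator recovers beta and Sigma in a mixed model", {
  beta <- c(0.2, 0.7, -0.4, 0.3)
  sig2 <- 0.25
  n_runs <- 20
  cover <- 0
  sig_means <- betas <- ses <- NULL
  for (r in seq_len(n_runs)) {
    ds <- make_mixed_logistic_dataset(2000, 50, beta, sig2,
                                      seed = 300 + r)
    fits <- fit_per_donor(ds, standardize = FALSE)
    mom <- moment_estimate(fits)
    betas <- rbind(betas, mom$beta_hat[-1])
    ses <- rbind(ses, mom$se)
    sig_means <- c(sig_means, mean(diag(mom$sigma_hat)[-1]))
    lo <- mom$beta_hat[-1] - qt(0.975, mom$df) * mom$se
    hi <- mom$beta_hat[-1] + qt(0.975, mom$df) * mom$se
    cover <- cover + mean(lo <= beta[-1] & beta[-1] <= hi)
  }
  # fixed effects unbiased within Monte-Carlo error
  mc_se <- apply(betas, 2, sd) / sqrt(n_runs)
  expect_true(all(abs(colMeans(betas) - beta[-1]) < 3 * mc_se))
  # random-effect variance within 25% on average
  expect_lt(abs(mean(sig_means) - sig2) / sig2, 0.25)
  # nominal 95% intervals cover at >= 85% (moment inference is
  # approximate)
  expect_gte(cover / n_runs, 0.85)
})

test_that("random-effect prediction obeys its shrinkage limits", {
  ds <- make_mixed_logistic_dataset(500, 5, c(0, 0.6, -0.2), 0.3,
                                    seed = 24)
  fits <- fit_per_donor(ds, standardize = FALSE)
  mom <- moment_estimate(fits)

  # Sigma = 0 => total shrinkage
  mom0 <- mom
  mom0$sigma_hat <- matrix(0, 3, 3)
  expect_equal(max(abs(predict_random_effects(mom0))), 0)

  # infinitely precise donor fits => no shrinkage
  mom_inf <- mom
  mom_inf$f_inv <- lapply(mom$f_inv, function(f) f * 0)
  u_free <- predict_random_effects(mom_inf)
  resid <- sweep(mom$theta, 2, mom$beta_hat)
  expect_equal(u_free, resid, tolerance = 1e-8,
               ignore_attr = TRUE)

  # the defining estimating equation holds exactly ...
  w <- lapply(mom$f_inv, function(fi) solve(mom$sigma_hat + fi))
  resid_w <- Reduce(`+`, Map(function(wj, j)
    wj %*% (mom$theta[j, ] - mom$beta_hat), w, seq_len(nrow(mom$theta))))
  expect_lt(max(abs(resid_w)), 1e-8)
  # ... so the precision-weighted mean of the shrunken effects is near
  # zero (approximate: Sigma and W_j do not commute exactly)
  u <- predict_random_effects(mom)
  wsum <- Reduce(`+`, w)
  wu <- Reduce(`+`, Map(function(wj, j) wj %*% u[j, ], w,
                        seq_len(nrow(u))))
  expect_lt(max(abs(solve(wsum, wu))), 0.05)
})

test_that("cytoglmm output is complete and label-flip antisymmetric", {
  ds <- make_mixed_logistic_dataset(400, 6, c(0, 0.8, -0.6), 0.2,
                                    seed = 25)
  fit <- cytoglmm(ds)
  expect_s3_class(fit, "cytoglmm_fit")
  expect_equal(fit$df, 5L)
  expect_true(all(fit$p_raw >= 0 & fit$p_raw <= 1))
  expect_true(all(eigen(fit$sigma_hat, symmetric = TRUE,
                        only.values = TRUE)$values >= -1e-10))
  expect_true(all(fit$se > 0))
  expect_equal(nrow(fit$u_hat), 6L)

  flipped <- cytometry_dataset(ds$expressions, donor = ds$donor,
                               condition = 1L - ds$condition)
  f2 <- cytoglmm(flipped)
  expect_equal(fit$beta_hat, -f2$beta_hat, tolerance = 1e-6)
  expect_equal(fit$p_raw, f2$p_raw, tolerance = 1e-8)
})
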