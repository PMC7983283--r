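test_that("ar1_covariance matches its closed form and is PSD", {
  expect_equal(ar1_covariance(c(1, 1, 1), 0), diag(3))
  s <- ar1_covariance(c(1, 1, 1), 0.4)
  expect_equal(s[1, 3], 0.16)
  expect_equal(s[1, 2], 0.4)
  expect_equal(ar1_covariance(c(2, 1), 0.5)[1, 2], 1.0)
  expect_error(ar1_covariance(c(1, 1), 1), "rho")
  expect_error(ar1_covariance(c(1, -1), 0.2), "nonnegative")
  set.seed(3)
  for (rho in c(-0.8, -0.4, 0.3, 0.7)) {
    sig <- ar1_covariance(runif(6, 0.5, 2), rho)
    expect_true(isSymmetric(sig))
    expect_gte(min(eigen(sig, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-12)
  }
})

test_that("default settings encode the two reference designs", {
  pp <- default_sim_params("paired")
  expect_equal(pp$n_donors, 8)
  expect_true(pp$paired)
  expect_equal(pp$delta1 - pp$delta0, c(rep(1.8, 3), rep(0, 7)))
  expect_equal(pp$n_cells_per_sample, 1000)
  expect_equal(pp$p, 10)
  up <- default_sim_params("unpaired")
  expect_equal(up$n_donors, 16)
  expect_false(up$paired)
  expect_equal(unique(up$delta1[1:3] - up$delta0[1:3]), 15)
})

test_that("simulated datasets have the declared paired/unpaired layout", {
  pr <- sim_params(n_donors = 4, n_cells_per_sample = 50)
  sim <- simulate_dataset(pr, seed = 1)
  ds <- sim$dataset
  expect_equal(nrow(ds$expressions), 2 * 4 * 50)
  expect_true(attr(ds, "paired"))
  tab <- table(ds$donor, ds$condition)
  expect_true(all(tab == 50))
  expect_true(all(ds$expressions >= 0))
  expect_true(all(ds$expressions == round(ds$expressions)))
  expect_equal(sim$truth$active, c(rep(TRUE, 3), rep(FALSE, 7)))

  up <- sim_params(n_donors = 6, n_cells_per_sample = 30, paired = FALSE,
                   effect = 1, delta0 = 1)
  du <- simulate_dataset(up, seed = 2)$dataset
  expect_false(attr(du, "paired"))
  expect_equal(nrow(du$expressions), 6 * 30)
  tab <- table(du$donor, du$condition)
  expect_true(all(rowSums(tab > 0) == 1))  # one condition per donor
  expect_equal(sum(colSums(tab) > 0), 2)   # both conditions present

  expect_error(simulate_dataset(sim_params(n_donors = 5, paired = FALSE)),
               "even number of donors")
})

test_that("fixed seeds reproduce draws and donor effects ignore cell count", {
  pr <- sim_params(n_donors = 3, n_cells_per_sample = 40)
  a <- simulate_dataset(pr, seed = 9)
  b <- simulate_dataset(pr, seed = 9)
  expect_identical(a$dataset$expressions, b$dataset$expressions)
  # U_j is drawn before cell-level quantities: growing the cell count
  # leaves the donor effects unchanged
  pr2 <- sim_params(n_donors = 3, n_cells_per_sample = 80)
  d <- simulate_dataset(pr2, seed = 9)
  expect_identical(a$truth$donor_effects, d$truth$donor_effects)
})

test_that("degenerate noise gives exact Poisson intensities", {
  # sigma_B = sigma_U = 0: every condition-y cell has lambda = exp(delta^y)
  pr <- sim_params(p = 4, active = 1:2, effect = 1, delta0 = log(20),
                   sigma_b = 0, sigma_u = 0, n_donors = 4,
                   n_cells_per_sample = 2000)
  sim <- simulate_dataset(pr, seed = 5)
  ds <- sim$dataset
  for (y in 0:1) {
    m <- colMeans(ds$expressions[ds$condition == y, ])
    lam <- exp(if (y == 0) pr$delta0 else pr$delta1)
    se <- sqrt(lam / sum(ds$condition == y))
    expect_true(all(abs(m - lam) < 4 * se))
  }
})

test_that("marginal count mean obeys the lognormal-Poisson identity", {
  # E[X] = exp(delta + (sigma_B^2 + sigma_U^2) / 2); Monte-Carlo check
  # with the standard error taken at the donor level (draws are
  # correlated within donors through U_j).
  pr <- sim_params(p = 2, active = integer(0), effect = 0, delta0 = 1,
                   sigma_b = 1, sigma_u = 1, n_donors = 100,
                   n_cells_per_sample = 500)
  sim <- simulate_dataset(pr, seed = 21)
  ds <- sim$dataset
  donor_means <- vapply(split(ds$expressions[, 1], ds$donor), mean,
                        numeric(1))
  se <- sd(donor_means) / sqrt(length(donor_means))
  expect_lt(abs(mean(donor_means) - exp(1 + 1)), 3 * se)
})

test_that("inactive markers are distributed identically across conditions", {
  pr <- sim_params(p = 3, active = 1L, effect = 2, delta0 = log(30),
                   n_donors = 60, n_cells_per_sample = 200)
  ds <- simulate_dataset(pr, seed = 31)$dataset
  x <- ds$expressions
  for (p in 2:3) {
    d0 <- x[ds$condition == 0, p]
    d1 <- x[ds$condition == 1, p]
    # paired design shares U_j across conditions: cell-level comparison
    se <- sqrt(var(d0) / length(d0) + var(d1) / length(d1))
    expect_lt(abs(mean(d1) - mean(d0)), 4 * se)
  }
  # the active marker separates clearly
  expect_gt(mean(x[ds$condition == 1, 1]), 2 * mean(x[ds$condition == 0, 1]))
})

test_that("donor effects are drawn from the requested AR(1) covariance", {
  pr <- sim_params(p = 4, sigma_u = 1.5, rho_u = 0.5, n_donors = 4000,
                   n_cells_per_sample = 1)
  u <- simulate_dataset(pr, seed = 13)$truth$donor_effects
  target <- ar1_covariance(rep(1.5, 4), 0.5)
  err <- norm(cov(u) - target, "F") / norm(target, "F")
  expect_lt(err, 0.1)
})

test_that("intensity overflow is caught by the configurable cap", {
  pr <- sim_params(delta0 = 40, n_donors = 2, n_cells_per_sample = 10,
                   lambda_cap = 1e12)
  expect_error(simulate_dataset(pr, seed = 1), "lambda_cap")
})
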