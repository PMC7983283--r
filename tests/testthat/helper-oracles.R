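# Shared fixtures and independent oracles for the test suite.

# Logistic data with known coefficients: x ~ N(0, I), y ~ Bern(logit^-1).
# Returns a cytometry_dataset whose markers are already on a unit scale,
# so fits with standardize = FALSE target `beta` directly.
make_logistic_dataset <- function(n, beta, n_donors = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta) - 1L
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("M", seq_len(p))))
  eta <- beta[1L] + x %*% beta[-1L]
  y <- rbinom(n, 1, plogis(eta))
  cytometry_dataset(x, donor = rep_len(seq_len(n_donors), n), condition = y)
}

# Mixed logistic data: each donor gets its own coefficient vector
# beta + u_j with u_j ~ N(0, diag(sigma2)). Every donor sees both
# conditions (y is the response, not a design label).
make_mixed_logistic_dataset <- function(n_per_donor, n_donors, beta,
                                        sigma2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta) - 1L
  xs <- ys <- ds <- vector("list", n_donors)
  for (j in seq_len(n_donors)) {
    bj <- beta + rnorm(length(beta), 0, sqrt(sigma2))
    x <- matrix(rnorm(n_per_donor * p), n_per_donor, p)
    y <- rbinom(n_per_donor, 1, plogis(bj[1L] + x %*% bj[-1L]))
    xs[[j]] <- x; ys[[j]] <- y; ds[[j]] <- rep(j, n_per_donor)
  }
  x <- do.call(rbind, xs)
  colnames(x) <- paste0("M", seq_len(p))
  cytometry_dataset(x, donor = unlist(ds), condition = unlist(ys))
}

# Direct step-up implementations of the BH and BY rejection rules,
# independent of stats::p.adjust: reject the k largest-ranked p-values
# below their step-up thresholds.
stepup_reject <- function(p, q, method = c("bh", "by")) {
  method <- match.arg(method)
  m <- length(p)
  cm <- if (method == "by") sum(1 / seq_len(m)) else 1
  o <- order(p)
  thresh <- seq_len(m) * q / (m * cm)
  below <- p[o] <= thresh
  k <- if (any(below)) max(which(below)) else 0L
  rejected <- logical(m)
  if (k > 0L) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

# Step-up adjusted p-values by the textbook cumulative-minimum formula.
stepup_adjust <- function(p, method = c("bh", "by")) {
  method <- match.arg(method)
  m <- length(p)
  cm <- if (method == "by") sum(1 / seq_len(m)) else 1
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m * cm * p[o] / (m:1)))
  adj[order(o)]
}

# Small on-disk CSV fixture: 4 cells, 2 markers, 2 donors, conditions A/B.
write_toy_csv <- function(path) {
  writeLines(c("donor,condition,CD38,HLADR",
               "d1,A,0.5,1.25",
               "d1,B,1.5,0.25",
               "d2,A,0.75,2.5",
               "d2,B,2.25,0.125"), path)
  path
}
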