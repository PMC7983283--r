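#' Observed FDR and power of a discovery set
#'
#' Observed false discovery proportion: false discoveries over total
#' discoveries, with the 0/0 (no discoveries) case defined as 0. Power:
#' recovered active markers over the number of truly active markers.
#'
#' @param discovered integer indices (or logical vector) of markers called
#'   differential.
#' @param truth a `ground_truth` from [simulate_dataset()], or a logical
#'   vector marking the active markers.
#' @return named numeric vector `c(fdr, power)`
#' @export
fdr_power <- function(discovered, truth) {
  active <- if (inherits(truth, "ground_truth")) truth$active else truth
  stopifnot(is.logical(active))
  if (is.logical(discovered)) discovered <- which(discovered)
  if (!sum(active)) stop("power is undefined with no active markers")
  n_disc <- length(discovered)
  n_false <- sum(!active[discovered])
  c(fdr = if (n_disc == 0L) 0 else n_false / n_disc,
    power = sum(active[discovered]) / sum(active))
}

study_methods <- c("glm_bh", "glm_by", "glmm_bh", "glmm_by")

# Deterministic child seed in [1, 2^31 - 2], keyed by root seed, a scenario
# label and a run index, so grid results do not depend on evaluation order.
child_seed <- function(seed, key, run) {
  h <- sum(utf8ToInt(as.character(key)) *
             (31^(seq_along(utf8ToInt(as.character(key))) %% 7)))
  as.integer((as.numeric(seed) * 48271 + h * 16807 + run * 69621) %%
               2147483629 + 1)
}

#' One simulation replicate: simulate, fit, adjust, score
#'
#' Draws one dataset from `params`, applies the transform, fits the
#' requested method families (the GLM once per replicate, shared by
#' `glm_bh`/`glm_by`; likewise the GLMM), thresholds adjusted p-values at
#' `target_q`, and scores the discovery sets against the ground truth.
#'
#' @param params a [sim_params()] object.
#' @param methods subset of `"glm_bh"`, `"glm_by"`, `"glmm_bh"`,
#'   `"glmm_by"`. GLMM methods require a paired design.
#' @param target_q FDR target used for discovery calls.
#' @param seed integer seed for this replicate (simulation and bootstrap).
#' @param transform [transform_spec()] applied to the simulated counts
#'   before fitting; default asinh with cofactor 5.
#' @param boot_b bootstrap replicates for the GLM methods.
#' @param standardize passed to the fitters.
#' @return data.frame with one row per method: `method`, `fdr`, `power`,
#'   `n_discoveries`.
#' @export
run_replicate <- function(params, methods = study_methods,
                          target_q = 0.05, seed = 1,
                          transform = transform_spec("asinh", 5),
                          boot_b = 200, standardize = TRUE) {
  methods <- match.arg(methods, study_methods, several.ok = TRUE)
  if (!params$paired && any(grepl("^glmm", methods)))
    stop("GLMM methods require a paired design")
  sim <- simulate_dataset(params, seed = seed)
  dataset <- sim$dataset
  dataset$expressions <- transform_expressions(dataset$expressions,
                                               transform)
  p_adj <- list()
  if (any(grepl("^glm_", methods))) {
    fit <- cytoglm(dataset, B = boot_b, standardize = standardize)
    p_adj$glm_bh <- fit$p_adj_bh
    p_adj$glm_by <- fit$p_adj_by
  }
  if (any(grepl("^glmm_", methods))) {
    fit <- cytoglmm(dataset, standardize = standardize)
    p_adj$glmm_bh <- fit$p_adj_bh
    p_adj$glmm_by <- fit$p_adj_by
  }
  rows <- lapply(methods, function(m) {
    disc <- which(p_adj[[m]] <= target_q)
    fp <- fdr_power(disc, sim$truth)
    data.frame(method = m, fdr = fp[["fdr"]], power = fp[["power"]],
               n_discoveries = length(disc))
  })
  do.call(rbind, rows)
}

#' Run a grid of simulation scenarios
#'
#' Averages observed FDR and power over `n_runs` independent replicates
#' for every scenario/method combination. Each replicate gets a child seed
#' derived from the root seed, the scenario label and the run index, so
#' results are invariant to the order scenarios are evaluated in.
#'
#' @param scenarios named list of [sim_params()] objects.
#' @param n_runs replicates per scenario.
#' @inheritParams run_replicate
#' @param seed root seed.
#' @return data.frame (class `study_summary`) in long format: `scenario`,
#'   `method`, `fdr`, `power`, `fdr_se`, `power_se` (Monte-Carlo standard
#'   errors, sd/sqrt(n_runs)), `n_runs`.
#' @export
run_grid <- function(scenarios, methods = study_methods, n_runs = 50,
                     target_q = 0.05, seed = 1,
                     transform = transform_spec("asinh", 5),
                     boot_b = 200, standardize = TRUE) {
  stopifnot(n_runs >= 1, length(scenarios) >= 1)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  out <- lapply(names(scenarios), function(sc) {
    reps <- lapply(seq_len(n_runs), function(r)
      run_replicate(scenarios[[sc]], methods = methods,
                    target_q = target_q,
                    seed = child_seed(seed, sc, r), transform = transform,
                    boot_b = boot_b, standardize = standardize))
    reps <- do.call(rbind, reps)
    agg <- lapply(split(reps, reps$method), function(d)
      data.frame(scenario = sc, method = d$method[1L],
                 fdr = mean(d$fdr), power = mean(d$power),
                 fdr_se = sd(d$fdr) / sqrt(nrow(d)),
                 power_se = sd(d$power) / sqrt(nrow(d)),
                 n_runs = nrow(d)))
    do.call(rbind, agg)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("study_summary", "data.frame")
  out
}

#' Donor sample-size scan with 80% power crossing
#'
#' Re-runs the scenario over an ascending list of donor counts and reports,
#' per method, the smallest donor count whose mean power exceeds the
#' threshold (NA if it is never exceeded).
#'
#' @param base_params a [sim_params()] template; its `n_donors` field is
#'   overridden by each element of `donor_counts`.
#' @param donor_counts ascending integer vector of donor numbers to scan.
#' @param power_threshold crossing threshold, default 0.8.
#' @inheritParams run_grid
#' @return list with `summary` (a [run_grid()] table with a `n_donors`
#'   column) and `crossing` (named integer vector, per method)
#' @export
sample_size_scan <- function(base_params, donor_counts = 4:14,
                             methods = study_methods, n_runs = 50,
                             target_q = 0.05, seed = 1,
                             power_threshold = 0.8,
                             transform = transform_spec("asinh", 5),
                             boot_b = 200, standardize = TRUE) {
  if (is.unsorted(donor_counts))
    stop("donor_counts must be ascending")
  donor_counts <- as.integer(donor_counts)
  scenarios <- lapply(donor_counts, function(j) {
    pr <- base_params
    pr$n_donors <- j
    pr
  })
  names(scenarios) <- paste0("donors_", donor_counts)
  summary <- run_grid(scenarios, methods = methods, n_runs = n_runs,
                      target_q = target_q, seed = seed,
                      transform = transform, boot_b = boot_b,
                      standardize = standardize)
  summary$n_donors <- donor_counts[match(summary$scenario,
                                         paste0("donors_", donor_counts))]
  crossing <- vapply(methods, function(m) {
    d <- summary[summary$method == m, ]
    d <- d[order(d$n_donors), ]
    hit <- which(d$power > power_threshold)
    if (length(hit)) d$n_donors[min(hit)] else NA_integer_
  }, integer(1))
  list(summary = summary, crossing = crossing)
}
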