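#' BH / BY false discovery rate adjustment
#'
#' Step-up FDR control: Benjamini-Hochberg (`"bh"`, valid under
#' independence or positive regression dependence) or Benjamini-Yekutieli
#' (`"by"`, valid under arbitrary dependence; BH thresholds inflated by
#' the harmonic factor `c(m) = sum(1/i)`). Adjustment is delegated to
#' [stats::p.adjust()]. `NaN`/`NA` p-values (e.g. from failed fits) are
#' excluded from the family with a warning and stay `NA` in the output.
#'
#' @param p raw p-values in \[0, 1\].
#' @param method `"bh"` or `"by"`.
#' @param q target FDR used to mark rejections; default 0.05.
#' @return an object of class `adjusted_pvals`: list with `p_raw`, `p_adj`,
#'   `method`, `q`, and logical `rejected` (`p_adj <= q`).
#' @export
adjust_pvalues <- function(p, method = c("bh", "by"), q = 0.05) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(!ok))
    warning(sum(!ok), " missing p-value(s) excluded from the family")
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p_adj <- rep(NA_real_, length(p))
  p_adj[ok] <- p.adjust(p[ok], method = toupper(method))
  rejected <- !is.na(p_adj) & p_adj <= q
  structure(list(p_raw = p, p_adj = setNames(p_adj, names(p)),
                 method = method, q = q, rejected = rejected),
            class = "adjusted_pvals")
}

#' Combine p-value tables from several two-group analyses
#'
#' For more than two experimental groups, run one two-group analysis per
#' pair and pool all (analysis, marker) hypotheses into a single family so
#' the FDR is controlled over the whole study, not per pair.
#'
#' @param results named list of per-analysis tables; each element is a
#'   data.frame with columns `marker` and `p` (the [marker_table()] output
#'   of either fitter works directly).
#' @param q target FDR.
#' @return data.frame with columns `analysis`, `marker`, `p`, `p_bh`,
#'   `p_by`, `rejected_bh`, `rejected_by`, adjusted over the pooled family.
#' @export
summarize_analyses <- function(results, q = 0.05) {
  if (length(results) == 0L) stop("no analyses to combine")
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("analysis", seq_along(results))
  tabs <- lapply(names(results), function(a) {
    tab <- results[[a]]
    if (inherits(tab, "cytoglm_fit") || inherits(tab, "cytoglmm_fit"))
      tab <- marker_table(tab)
    if (!all(c("marker", "p") %in% names(tab)))
      stop("each table needs 'marker' and 'p' columns")
    data.frame(analysis = a, marker = tab$marker, p = tab$p)
  })
  out <- do.call(rbind, tabs)
  key <- paste(out$analysis, out$marker, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (analysis, marker) hypotheses: ",
         paste(unique(out$marker[duplicated(key)]), collapse = ", "))
  bh <- adjust_pvalues(out$p, "bh", q = q)
  by <- adjust_pvalues(out$p, "by", q = q)
  out$p_bh <- unname(bh$p_adj)
  out$p_by <- unname(by$p_adj)
  out$rejected_bh <- bh$rejected
  out$rejected_by <- by$rejected
  out
}
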