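#' Selection thresholds for biomarkers and endogenous controls
#'
#' Bundles the filter thresholds used by [select_degs()] and
#' [select_ecs()]:
#'
#' * `deg_p_max` — maximum raw p-value for a differentially expressed
#'   biomarker (default 0.05, inclusive).
#' * `deg_lfc_min` — minimum |log2 fold change| for a biomarker (default 0;
#'   raise to e.g. 1 to prioritize high-impact candidates).
#' * `ec_p_min` — minimum p-value for an endogenous control (default 0.8,
#'   inclusive; values down to 0.6 are a reasonable relaxation for small
#'   cohorts).
#' * `ec_lfc_max` — strict upper bound on |log2 fold change| for a control
#'   (default 0.02).
#' * `min_mean_norm` — expression floor in mean normalized counts applied
#'   to both selections (default 100); a control with near-zero counts is
#'   unusable as a PCR denominator.
#'
#' P-value thresholds apply to raw Wald p-values, not FDR; column names in
#' the outputs make this explicit.
#'
#' @param deg_p_max,deg_lfc_min,ec_p_min,ec_lfc_max,min_mean_norm See above.
#' @return A list of class `"selection_thresholds"`.
#' @export
selection_thresholds <- function(deg_p_max = 0.05, deg_lfc_min = 0,
                                 ec_p_min = 0.8, ec_lfc_max = 0.02,
                                 min_mean_norm = 100) {
  th <- list(deg_p_max = deg_p_max, deg_lfc_min = deg_lfc_min,
             ec_p_min = ec_p_min, ec_lfc_max = ec_lfc_max,
             min_mean_norm = min_mean_norm)
  if (!(deg_p_max > 0 && deg_p_max <= 1)) abort_validation("deg_p_max must be in (0, 1]")
  if (deg_lfc_min < 0) abort_validation("deg_lfc_min must be >= 0")
  if (!(ec_p_min >= 0 && ec_p_min < 1)) abort_validation("ec_p_min must be in [0, 1)")
  if (ec_lfc_max <= 0) abort_validation("ec_lfc_max must be > 0")
  if (min_mean_norm < 0) abort_validation("min_mean_norm must be >= 0")
  structure(th, class = "selection_thresholds")
}

#' @export
print.selection_thresholds <- function(x, ...) {
  cat("Selection thresholds:\n")
  cat(sprintf("  DEG: raw p <= %g, |log2FC| >= %g\n", x$deg_p_max, x$deg_lfc_min))
  cat(sprintf("  EC : raw p >= %g, |log2FC| < %g\n", x$ec_p_min, x$ec_lfc_max))
  cat(sprintf("  expression floor: mean normalized count >= %g\n", x$min_mean_norm))
  invisible(x)
}

#' Select differentially expressed biomarkers
#'
#' Filters a differential expression table to genes with raw
#' `pvalue <= deg_p_max`, `|log2fc| >= deg_lfc_min` and
#' `base_mean >= min_mean_norm`, then ranks by p-value ascending, ties
#' broken by |log2fc| descending, then gene identifier. Genes with `NA`
#' p-values are never selected.
#'
#' @param res Result table from [nb_wald_test()].
#' @param th Thresholds from [selection_thresholds()].
#' @return The selected rows of `res`, ranked, with a `rank` column.
#' @export
select_degs <- function(res, th = selection_thresholds()) {
  stopifnot(inherits(th, "selection_thresholds"))
  if (nrow(res) == 0L) abort_validation("empty differential expression table")
  keep <- !is.na(res$pvalue) &
    res$pvalue <= th$deg_p_max &
    abs(res$log2fc) >= th$deg_lfc_min &
    res$base_mean >= th$min_mean_norm
  out <- res[keep, , drop = FALSE]
  ord <- order(out$pvalue, -abs(out$log2fc), out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out$rank <- seq_len(nrow(out)) else out$rank <- integer(0)
  out
}

#' Select endogenous control candidates
#'
#' Retains genes that look stable across the two groups: strict
#' `|log2fc| < ec_lfc_max`, raw `pvalue >= ec_p_min` and
#' `base_mean >= min_mean_norm`. Candidates are ranked by NB dispersion
#' ascending (`stability_rank` 1 = most stable, i.e. lowest combined
#' intra-group variability), ties broken by |log2fc| ascending, then gene
#' identifier. The dispersion enters only the ranking, never as a hard
#' cutoff.
#'
#' @inheritParams select_degs
#' @param disp Dispersion table from [estimate_dispersions()], aligned on
#'   gene identifiers.
#' @return A `data.frame` of candidates: `gene_id`, `log2fc`, `pvalue_raw`,
#'   `alpha`, `base_mean`, `stability_rank`. Empty (with a warning
#'   suggesting relaxed thresholds) when nothing passes.
#' @export
select_ecs <- function(res, disp, th = selection_thresholds()) {
  stopifnot(inherits(th, "selection_thresholds"))
  if (!setequal(res$gene_id, disp$gene_id)) {
    abort_validation("differential expression and dispersion tables disagree on gene identifiers")
  }
  alpha <- disp$alpha[match(res$gene_id, disp$gene_id)]
  keep <- !is.na(res$pvalue) &
    abs(res$log2fc) < th$ec_lfc_max &
    res$pvalue >= th$ec_p_min &
    res$base_mean >= th$min_mean_norm
  out <- data.frame(gene_id = res$gene_id, log2fc = res$log2fc,
                    pvalue_raw = res$pvalue, alpha = alpha,
                    base_mean = res$base_mean,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning(paste0("no endogenous control candidate passed the stability filter; ",
                   "consider relaxing ec_p_min (recommended floor 0.6) or ec_lfc_max"),
            call. = FALSE)
  }
  ord <- order(out$alpha, abs(out$log2fc), out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$stability_rank <- seq_len(nrow(out))
  out
}

#' Stability report table
#'
#' Candidate endogenous controls ordered by stability rank with all
#' supporting statistics, ready for [write_results_csv()].
#'
#' @param ecs Candidate table from [select_ecs()].
#' @return A `data.frame` ordered by `stability_rank`.
#' @export
stability_report <- function(ecs) {
  cols <- c("stability_rank", "gene_id", "alpha", "log2fc", "pvalue_raw", "base_mean")
  out <- ecs[order(ecs$stability_rank), intersect(cols, colnames(ecs)), drop = FALSE]
  rownames(out) <- NULL
  out
}
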