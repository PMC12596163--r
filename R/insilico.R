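#' Per-sample biomarker / endogenous-control count ratios
#'
#' In silico analogue of a ratio-based ddPCR readout: for each sample, the
#' biomarker's raw count divided by the candidate endogenous control's raw
#' count. Raw counts are used deliberately — per-sample size factors cancel
#' in the ratio, exactly as technical scale cancels in a ddPCR
#' target/reference ratio. A higher ratio means higher biomarker expression
#' relative to the control (note this is the inverse direction of a qPCR
#' delta-Ct; see [flip_direction()]).
#'
#' @inheritParams estimate_size_factors
#' @param biomarker,ec Gene identifiers; must differ.
#' @param zero_policy `"exclude"` (default) drops samples whose control
#'   count is zero and records them in `excluded_samples` — mirroring ddPCR
#'   practice, where an undetected reference invalidates the well.
#'   `"pseudocount"` instead computes `(biomarker + 0.5) / (ec + 0.5)` for
#'   every sample.
#' @return An object of class `"ratio_comparison"`: list with
#'   `biomarker`, `ec`, `sample_ids`, `ratios`, `excluded_samples`, and
#'   empty test fields (`groups`, `wilcoxon_p`, `stars`, `direction`) to be
#'   filled by [test_ratio()].
#' @export
normalization_ratio <- function(counts, biomarker, ec, zero_policy = c("exclude", "pseudocount")) {
  zero_policy <- match.arg(zero_policy)
  validate_count_matrix(counts)
  for (g in c(biomarker, ec)) {
    if (!g %in% rownames(counts)) abort_key(sprintf("unknown gene '%s'", g))
  }
  if (identical(biomarker, ec)) {
    abort_validation("biomarker and endogenous control must be different genes")
  }
  b <- counts[biomarker, ]
  e <- counts[ec, ]
  if (all(e == 0)) {
    abort_validation(sprintf("endogenous control '%s' has zero counts in every sample", ec))
  }
  if (zero_policy == "pseudocount") {
    ratios <- (b + 0.5) / (e + 0.5)
    excluded <- character(0)
  } else {
    keep <- e > 0
    ratios <- b[keep] / e[keep]
    excluded <- colnames(counts)[!keep]
  }
  structure(list(biomarker = biomarker, ec = ec,
                 sample_ids = names(ratios), ratios = unname(ratios),
                 excluded_samples = excluded, zero_policy = zero_policy,
                 groups = NULL, wilcoxon_p = NULL, stars = NULL, direction = NULL),
            class = "ratio_comparison")
}

#' Wilcoxon rank-sum validation of a ratio comparison
#'
#' Splits the per-sample ratios by the two-level group factor, runs a
#' two-sided Wilcoxon rank-sum test, and annotates the comparison with the
#' p-value, its significance stars and the effect direction
#' (`sign(median ratio in the non-reference group - median ratio in the
#' reference group)`).
#'
#' @param rc A `"ratio_comparison"` from [normalization_ratio()].
#' @param meta Metadata with the two-level `group` factor.
#' @param mode Passed to [wilcoxon_rank_sum()].
#' @return `rc` with `groups`, `wilcoxon_p`, `stars` and `direction` filled.
#' @export
test_ratio <- function(rc, meta, mode = "auto") {
  stopifnot(inherits(rc, "ratio_comparison"))
  grp <- check_group(meta)
  names(grp) <- rownames(meta)
  missing <- setdiff(rc$sample_ids, names(grp))
  if (length(missing)) {
    abort_validation(sprintf("samples absent from metadata: %s", paste(missing, collapse = ", ")))
  }
  g <- droplevels(grp[rc$sample_ids])
  lev <- levels(grp)
  a <- rc$ratios[g == lev[1L]]
  b <- rc$ratios[g == lev[2L]]
  if (!length(a) || !length(b)) {
    abort_validation(sprintf(
      "group '%s' has no usable samples after zero-count exclusion; consider zero_policy = 'pseudocount'",
      lev[which(c(length(a), length(b)) == 0L)[1L]]))
  }
  rc$groups <- as.character(g)
  rc$wilcoxon_p <- wilcoxon_rank_sum(a, b, mode = mode)
  rc$stars <- significance_stars(rc$wilcoxon_p)
  rc$direction <- sign(stats::median(b) - stats::median(a))
  rc
}

#' @export
print.ratio_comparison <- function(x, ...) {
  cat(sprintf("In-silico normalization: %s / %s (%d samples", x$biomarker, x$ec,
              length(x$ratios)))
  if (length(x$excluded_samples)) {
    cat(sprintf(", %d excluded for zero control counts", length(x$excluded_samples)))
  }
  cat(")\n")
  if (!is.null(x$wilcoxon_p)) {
    cat(sprintf("  Wilcoxon rank-sum p = %.4g [%s], direction %+d\n",
                x$wilcoxon_p, x$stars, x$direction))
  }
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) p-value
#'
#' `mode = "exact"` uses the exact null distribution of the rank-sum
#' statistic (no ties); `"normal"` uses the normal approximation with
#' tie-corrected variance and continuity correction; `"auto"` (default)
#' picks exact when the combined sample size is at most 20 and the data are
#' tie-free, otherwise the approximation. When ties make the exact
#' distribution unavailable, the approximation is used with a warning.
#' Delegates to [stats::wilcox.test()].
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) abort_validation("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) abort_validation("ratios must not contain NA")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(mode,
                  exact = TRUE,
                  normal = FALSE,
                  auto = (length(a) + length(b)) <= 20L && !ties)
  if (exact && ties) {
    warning("ties present: exact Wilcoxon distribution unavailable, using the normal approximation",
            call. = FALSE)
    exact <- FALSE
  }
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Significance stars
#'
#' Maps a p-value to the conventional star annotation: `***` for p <=
#' 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort_validation("p-values must lie in [0, 1]")
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns")))
}

#' Flip the effect direction of a ratio comparison
#'
#' Count ratios and qPCR delta-Ct run in opposite directions (a lower
#' delta-Ct means higher expression). This helper negates the recorded
#' direction while leaving ratios and the p-value untouched, so boxplot
#' annotations can be read in delta-Ct convention.
#'
#' @param rc A `"ratio_comparison"`.
#' @return `rc` with `direction` negated.
#' @export
flip_direction <- function(rc) {
  stopifnot(inherits(rc, "ratio_comparison"))
  if (!is.null(rc$direction)) rc$direction <- -rc$direction
  rc
}

#' Compare biomarkers across candidate endogenous controls
#'
#' Runs the full biomarker x control grid of in-silico normalizations with
#' Wilcoxon validation and reports, per pair, whether the ratio test
#' *recapitulates* the biomarker's differential expression: significant at
#' p <= 0.05 with the ratio's direction matching the sign of the
#' biomarker's log2 fold change. The fraction of recapitulated biomarkers
#' is the figure of merit for a candidate control — a control that is
#' itself differentially expressed cancels the biomarker signal and drags
#' this fraction toward zero.
#'
#' @inheritParams normalization_ratio
#' @param meta Metadata with the two-level `group` factor.
#' @param biomarkers,ecs Character vectors of gene identifiers.
#' @param res Optional [nb_wald_test()] table supplying each biomarker's
#'   log2 fold change. Without it the direction concordance (and hence
#'   recapitulation) is `NA`.
#' @param reference_level Reference group level; default the first level.
#' @return A `data.frame`, one row per biomarker x control pair:
#'   sample counts per group, excluded-sample count, group median ratios,
#'   `direction`, `wilcoxon_p`, `stars`, `de_log2fc`, `recapitulated`.
#' @export
compare_ecs <- function(counts, meta, biomarkers, ecs, res = NULL,
                        zero_policy = "exclude", reference_level = NULL) {
  validate_count_matrix(counts)
  meta <- align_metadata(counts, meta)
  grp <- check_group(meta)
  if (!is.null(reference_level)) grp <- stats::relevel(grp, ref = reference_level)
  meta2 <- data.frame(group = grp, row.names = rownames(meta))
  lev <- levels(grp)
  rows <- list()
  for (bm in biomarkers) {
    de_lfc <- if (!is.null(res)) res$log2fc[match(bm, res$gene_id)] else NA_real_
    for (ec in ecs) {
      rc <- normalization_ratio(counts, bm, ec, zero_policy = zero_policy)
      rc <- test_ratio(rc, meta2)
      g <- rc$groups
      recap <- if (is.na(de_lfc)) NA else {
        rc$wilcoxon_p <= 0.05 && rc$direction != 0 && rc$direction == sign(de_lfc)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        biomarker = bm, ec = ec,
        n_ref = sum(g == lev[1L]), n_alt = sum(g == lev[2L]),
        n_excluded = length(rc$excluded_samples),
        median_ratio_ref = stats::median(rc$ratios[g == lev[1L]]),
        median_ratio_alt = stats::median(rc$ratios[g == lev[2L]]),
        direction = rc$direction, wilcoxon_p = rc$wilcoxon_p, stars = rc$stars,
        de_log2fc = de_lfc, recapitulated = recap,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "recapitulation_rule") <-
    "recapitulated = (wilcoxon_p <= 0.05) AND sign(ratio direction) == sign(biomarker log2fc)"
  out
}
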