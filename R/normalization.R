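#' Median-of-ratios size factors
#'
#' Estimates one positive scaling constant per sample by the
#' median-of-ratios method: each gene's counts are divided by that gene's
#' geometric mean across samples, and the sample's size factor is the median
#' of those ratios over the reference gene set. Genes with any zero count
#' are excluded from the reference set (their geometric mean would be zero).
#' Factors are rescaled to geometric mean 1 so that normalized counts stay
#' on the raw-count scale.
#'
#' @param counts Integer count matrix (genes x samples), see
#'   [validate_count_matrix()].
#' @param pseudo_reference If `TRUE`, the reference geometric means are
#'   computed from `counts + 1` over all genes instead of restricting to
#'   all-positive genes. Use when every gene contains at least one zero
#'   (sparse miRNA or single-cell matrices), where the default reference
#'   set is empty.
#' @return Named numeric vector of size factors, one per sample, geometric
#'   mean 1.
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 200, seed = 1))
#' sf <- estimate_size_factors(sim$counts)
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  validate_count_matrix(counts)
  # median taken over the ratios themselves (an even reference set uses the
  # arithmetic midpoint of the two central ratios)
  if (pseudo_reference) {
    geo <- exp(rowMeans(log(counts + 1)))
    ratios <- counts / geo                  # zero counts give ratio 0
    f <- apply(ratios, 2L, function(r) stats::median(r[r > 0]))
    if (anyNA(f) || any(!is.finite(f) | f <= 0)) {
      abort_estimation("pseudo-reference size factors undefined: a sample has no positive counts")
    }
  } else {
    keep <- rowSums(counts > 0) == ncol(counts)
    if (!any(keep)) {
      abort_estimation(paste0(
        "every gene has at least one zero count, so the median-of-ratios ",
        "reference set is empty; filter low-count genes or use pseudo_reference = TRUE"))
    }
    ref <- counts[keep, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
    f <- apply(ref / geo, 2L, stats::median)
  }
  f <- f / exp(mean(log(f)))                # rescale to geometric mean 1
  names(f) <- colnames(counts)
  f
}

#' Normalize counts by size factors
#'
#' Divides each sample's column by its size factor, correcting library-size
#' and compositional differences while keeping values on the raw-count
#' scale (size factors have geometric mean 1).
#'
#' @inheritParams estimate_size_factors
#' @param sf Named size factor vector from [estimate_size_factors()].
#' @return Numeric matrix of normalized counts, same dimnames as `counts`.
#' @export
normalize_counts <- function(counts, sf) {
  validate_count_matrix(counts)
  if (is.null(names(sf))) {
    if (length(sf) != ncol(counts)) abort_validation("size factors must match sample count")
    names(sf) <- colnames(counts)
  }
  if (!setequal(names(sf), colnames(counts))) {
    abort_validation(sprintf(
      "size factor samples differ from count matrix samples: [%s] vs [%s]",
      paste(setdiff(names(sf), colnames(counts)), collapse = ", "),
      paste(setdiff(colnames(counts), names(sf)), collapse = ", ")))
  }
  sf <- sf[colnames(counts)]
  if (any(!is.finite(sf)) || any(sf <= 0)) abort_validation("size factors must be positive and finite")
  sweep(counts, 2L, sf, "/")
}

#' Mean normalized count of one gene
#'
#' Arithmetic mean of a gene's normalized counts across all samples — the
#' expression level against which the selection floor (default 100
#' normalized counts) is applied.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param gene Gene identifier.
#' @return Non-negative scalar.
#' @export
mean_normalized_count <- function(norm, gene) {
  if (!gene %in% rownames(norm)) abort_key(sprintf("unknown gene '%s'", gene))
  mean(norm[gene, ])
}
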