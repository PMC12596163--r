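#' Row-wise z-scores
#'
#' Centers and scales each row to mean 0, standard deviation 1. Constant
#' rows (zero variance) become all-zero rows rather than `NaN` — a flat
#' gene carries no pattern, so it is drawn as uniformly average.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Heatmap of selected genes
#'
#' Draws a genes-x-samples heatmap of row-z-scored `log2(normalized count
#' + 1)` values with a group annotation bar, via [pheatmap::pheatmap()].
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param meta Metadata with the `group` factor.
#' @param genes Character vector of at least 2 gene identifiers.
#' @param file Output path; format by extension (`.png`, `.pdf`, `.svg`).
#' @param cluster_rows Hierarchically cluster gene rows (default `FALSE`).
#' @return `file`, invisibly.
#' @export
plot_heatmap <- function(norm, meta, genes, file, cluster_rows = FALSE) {
  missing <- setdiff(genes, rownames(norm))
  if (length(missing)) abort_key(sprintf("unknown gene(s): %s", paste(missing, collapse = ", ")))
  if (length(genes) < 2L) abort_validation("heatmap needs at least 2 genes")
  meta <- meta[colnames(norm), , drop = FALSE]
  z <- zscore_rows(log2(norm[genes, , drop = FALSE] + 1))
  ann <- data.frame(group = meta$group, row.names = colnames(norm))
  ph <- pheatmap::pheatmap(z, annotation_col = ann, cluster_rows = cluster_rows,
                           cluster_cols = FALSE, silent = TRUE,
                           main = "Top genes (row z-score of log2 normalized counts)")
  with_device(file, {
    grid::grid.newpage()
    grid::grid.draw(ph$gtable)
  })
  invisible(file)
}

#' Volcano plot
#'
#' log2 fold change against -log10 raw p-value, with guide lines at the
#' selection thresholds and passing genes highlighted. Genes with `NA`
#' p-values are omitted; `p = 0` is clamped to the smallest positive
#' double before taking the logarithm.
#'
#' @param res Result table from [nb_wald_test()].
#' @param file Output path; format by extension.
#' @param p_max,lfc_min Guide-line thresholds (defaults 0.05 and 1).
#' @return `file`, invisibly.
#' @export
plot_volcano <- function(res, file, p_max = 0.05, lfc_min = 1) {
  pts <- volcano_points(res, p_max = p_max, lfc_min = lfc_min)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$log2fc, y = .data$neglog10p,
                                         colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d7301f", `FALSE` = "grey55"),
                                 guide = "none") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value") +
    ggplot2::theme_bw()
  with_device(file, print(p))
  invisible(file)
}

#' Data layer of the volcano plot
#'
#' The exact point set [plot_volcano()] draws, exposed so the plotted
#' quantities can be asserted on the table rather than on pixels.
#'
#' @inheritParams plot_volcano
#' @return `data.frame` with `gene_id`, `log2fc`, `neglog10p`,
#'   `significant`; one row per gene with a non-`NA` p-value.
#' @export
volcano_points <- function(res, p_max = 0.05, lfc_min = 1) {
  ok <- !is.na(res$pvalue)
  p <- pmax(res$pvalue[ok], .Machine$double.xmin)
  data.frame(gene_id = res$gene_id[ok], log2fc = res$log2fc[ok],
             neglog10p = -log10(p),
             significant = res$pvalue[ok] <= p_max & abs(res$log2fc[ok]) >= lfc_min,
             stringsAsFactors = FALSE)
}

#' Grouped boxplot of in-silico normalization ratios
#'
#' Per-group boxplots of biomarker/control count ratios with the Wilcoxon
#' significance stars drawn above, emulating a ratio-based ddPCR readout
#' figure.
#'
#' @param rc A `"ratio_comparison"`; if not yet tested it is passed through
#'   [test_ratio()] first.
#' @param meta Metadata with the `group` factor.
#' @param file Output path; format by extension.
#' @return `file`, invisibly.
#' @export
plot_ratio_boxplot <- function(rc, meta, file) {
  stopifnot(inherits(rc, "ratio_comparison"))
  if (is.null(rc$wilcoxon_p)) rc <- test_ratio(rc, meta)
  df <- data.frame(group = rc$groups, ratio = rc$ratios, stringsAsFactors = FALSE)
  ytop <- max(df$ratio) * 1.08
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$ratio,
                                        fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.7) +
    ggplot2::annotate("text", x = 1.5, y = ytop, label = rc$stars, size = 6) +
    ggplot2::labs(x = NULL, y = sprintf("%s / %s count ratio", rc$biomarker, rc$ec)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw()
  with_device(file, print(p))
  invisible(file)
}

# Open the graphics device matching the file extension, run the drawing
# code, close the device.
with_device <- function(file, code, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(file, width = width, height = height),
         svg = grDevices::svg(file, width = width, height = height),
         abort_validation(sprintf("unsupported image format '%s' (use png, pdf or svg)", ext)))
  on.exit(grDevices::dev.off())
  force(code)
  invisible(file)
}
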